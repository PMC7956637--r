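# Bundled demonstration specs whose schedules realize the published
# per-helix occupancy statistics of the apo and holo TSPO systems exactly by
# construction. They are the worked inputs for the acceptance script and the
# vignette, not fitted objects: the per-helix percentages, the TM V mean
# occupancy, the simultaneous CRAC/CARC frame count and the apo/holo bound
# ratio are encoded as deterministic frame schedules.

#' @noRd
demo_motif_regions <- function() {
  list(CRAC = c(150, 156), CARC = c(135, 141), "CRAC-like" = c(17, 24),
       LAF = c(144, 146))
}

#' Demonstration spec: apo-like system
#'
#' 1000 frames at 1 ns stride. Deterministic cholesterol schedules give
#' per-helix occupancies of 32/51/23/27/100 percent (TM I-TM V), a TM V mean
#' occupancy of 1.5 cholesterol per frame (one molecule on CRAC throughout,
#' a second on CARC for half the run, i.e. 500 frames of simultaneous
#' distinct-molecule CRAC+CARC binding), and 2850 total bound events. TM I
#' carries a 51 degree kink.
#'
#' @param n_frames Frame count (default 1000).
#' @param seed Seed for the (bounded) thermal noise.
#' @return A [synthetic_spec()].
#' @export
demo_apo_spec <- function(n_frames = 1000L, seed = 101L) {
  hx <- default_helices()
  hx[[1]]$kink_pos <- 15L        # proline-like hinge in TM I
  hx[[1]]$kink_angle <- 51
  sc <- function(mol, region, upto, target, from = 1L)
    list(mol = mol, region = region,
         frames = if (upto >= from) seq.int(from, upto) else integer(0),
         target_residue = target)
  f <- function(x) as.integer(round(x * n_frames / 1000))
  synthetic_spec(
    helices = hx,
    chol_schedule = list(
      sc(1, "TM I", f(320), 8L),
      sc(7, "TM I", f(20), 9L),
      sc(2, "TM II", f(510), 57L),
      sc(3, "TM III", f(230), 90L),
      sc(4, "TM IV", f(270), 121L),
      sc(5, "CRAC", n_frames, 151L),
      sc(6, "CARC", f(500), 138L)),
    regions = demo_motif_regions(),
    n_frames = n_frames, sigma = 0.12, clip = 0.45, seed = seed)
}

#' Demonstration spec: holo-like system
#'
#' As [demo_apo_spec()] but with the ligand bound: per-helix occupancies
#' 47/26/19/15/48 percent, cholesterol on the TM I CRAC-like motif and on
#' CRAC only (no CARC binding, so simultaneous binding is abolished), 1900
#' total bound events (apo/holo ratio 1.5), a gently kinked TM I (10
#' degrees), constant ligand binders at full residence, frequent binders at
#' 0.80/0.76, and a W53-carbonyl H-bond present in 60 percent of frames.
#'
#' @inheritParams demo_apo_spec
#' @return A [synthetic_spec()].
#' @export
demo_holo_spec <- function(n_frames = 1000L, seed = 202L) {
  hx <- default_helices()
  hx[[1]]$kink_pos <- 15L
  hx[[1]]$kink_angle <- 10
  sc <- function(mol, region, upto, target, from = 1L)
    list(mol = mol, region = region,
         frames = if (upto >= from) seq.int(from, upto) else integer(0),
         target_residue = target)
  f <- function(x) as.integer(round(x * n_frames / 1000))
  synthetic_spec(
    helices = hx,
    chol_schedule = list(
      sc(1, "CRAC-like", f(470), 20L),
      sc(7, "TM I", f(350), 10L),
      sc(2, "TM II", f(260), 57L),
      sc(3, "TM III", f(190), 90L),
      sc(4, "TM IV", f(150), 121L),
      sc(5, "CRAC", f(480), 151L)),
    ligand_schedule = list(
      contacts = list(
        `22` = seq_len(n_frames), `25` = seq_len(n_frames),
        `53` = seq_len(n_frames), `95` = seq_len(n_frames),
        `147` = seq_len(n_frames), `150` = seq_len(n_frames),
        `49` = seq_len(f(800)), `96` = seq_len(f(760)),
        `21` = seq.int(f(800) + 1L, n_frames)),
      hbond = list(residue = 53L, frames = seq_len(f(600)))),
    regions = demo_motif_regions(),
    n_frames = n_frames, sigma = 0.08, clip = 0.23, seed = seed)
}
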