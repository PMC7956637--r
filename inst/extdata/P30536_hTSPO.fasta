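>sp|P30536|TSPO_HUMAN Translocator protein OS=Homo sapiens GN=TSPO
MAPPWVPAMGFTLAPSLGCFVGSRFVHGEGLRWYAGLQKPSWHPPHWVLGPVWGTLYSAM
GYGSYLVWKELGGFTEKAVVPLGLYTGQLALNWAWPPIFFGARQMGWALVDLLLVSGAAA
ATTVAWYQVSPLAARLLYPYLAWLAFATTLNYCVWRDNHGWHGGRRLPE
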