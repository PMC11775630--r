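# Curated panel of proteins reported to aggregate in neurodegenerative
# disease, used as a targeted database for crosslink searching.  This is
# editable configuration, not ground truth: add or remove identifiers
# (gene symbols or accessions matching your FASTA) to change the panel.
MAPT
APP
SNCA
DPYSL2
CRMP1
DPYSL3
DPYSL4
GFAP
GAPDH
VDAC2
PLP1
CNP
DLAT
NEFL
NEFH
CAMK2A
ALDOA
PKM
MBP
UBB
SOD1
YWHAZ
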