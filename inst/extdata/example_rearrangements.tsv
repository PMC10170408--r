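amino_acid	templates	seq_reads	frame_type	v_resolved	j_resolved
CSLYIMCFVNYVNVWCRF	8	96	In	TCRBV07-01	TCRBJ02-04
CQYTDGRYQYMEVF	5	55	In	TCRBV03-01	TCRBJ01-05
CREYISRMEDLHNQSF	5	50	In	TCRBV15-01	TCRBJ02-06
CADKYNTPGHQYPCPF	5	40	In	TCRBV06-01	TCRBJ02-04
CKGQFLGLLDMMVGPF	5	35	In	TCRBV02-01	TCRBJ01-05
CDYEFAHWCLLQNKF	6	72	In	TCRBV26-01	TCRBJ02-03
CIRSAMRTHDQCDRIYVF	11	77	In	TCRBV24-01	TCRBJ01-04
CCYPVRWRTFSYLMF	9	90	In	TCRBV19-01	TCRBJ01-04
CCTYHWMTYTPAEIPEMQF	11	66	In	TCRBV29-01	TCRBJ02-04
CQMGHYVQVPCWHGF	7	84	In	TCRBV05-01	TCRBJ01-07
CWNLPPFVPYAFVAYWIF	5	55	In	TCRBV16-01	TCRBJ02-01
CAQYMKWFCKDNCSVTYIIF	5	45	In	TCRBV08-01	TCRBJ02-03
CMLWQRRFTVGF	5	45	In	TCRBV15-01	TCRBJ02-03
CAEYFSRPSRGLHF	5	60	In	TCRBV11-01	TCRBJ02-02
CSANPMNDWVENWFF	7	49	In	TCRBV04-01	TCRBJ01-01
CLFQGQWPYLPMRPIF	6	66	In	TCRBV08-01	TCRBJ02-07
CFYAPLYFTHLTQF	6	60	In	TCRBV06-01	TCRBJ01-03
CEKKSFTQEF	5	35	In	TCRBV25-01	TCRBJ02-07
CPNMFCVIEF	5	40	In	TCRBV07-01	TCRBJ01-04
CVDCHFQTCIQLVIWMLF	7	63	In	TCRBV06-01	TCRBJ01-05
CDMTNHSMMTKNNF	5	40	In	TCRBV22-01	TCRBJ01-01
CLPSNMIAQKF	5	40	In	TCRBV19-01	TCRBJ02-07
CEQHCKLYQWHWCQF	7	42	In	TCRBV10-01	TCRBJ02-07
CFLAEMIPSDSPVFVTF	6	72	In	TCRBV04-01	TCRBJ02-04
CENWKMNCHEWTCDCKLAF	5	35	In	TCRBV04-01	TCRBJ02-03
CPTAAKARVFWGWF	5	45	In	TCRBV10-01	TCRBJ01-03
CMKCWKGCCYKRLF	5	55	In	TCRBV14-01	TCRBJ02-05
CVWTKSGPFSF	5	45	In	TCRBV28-01	TCRBJ02-03
CTLDQMLRSLDAADPF	7	84	In	TCRBV30-01	TCRBJ01-02
CYTIFDMGLVMKFF	5	45	In	TCRBV28-01	TCRBJ02-06
CNYVECPTNHLGMPGF	6	48	In	TCRBV08-01	TCRBJ01-05
CACLKSGRSWWLISGF	6	60	In	TCRBV11-01	TCRBJ02-01
CKMRHLDYIKMHHYHDF	7	70	In	TCRBV18-01	TCRBJ02-05
CTPSRVKAEKWLCF	6	36	In	TCRBV03-01	TCRBJ01-02
CMEAIQAIWPCKPWIF	6	42	In	TCRBV21-01	TCRBJ01-01
CLATQGMSTCGF	5	50	In	TCRBV18-01	TCRBJ02-04
CGRLKCMCLLTDF	6	48	In	TCRBV27-01	TCRBJ02-02
CYCNACQCFTFQF	5	30	In	TCRBV13-01	TCRBJ01-06
CLYDQVFIHF	8	64	In	TCRBV25-01	TCRBJ02-05
CGANDLKLTWAGGLF	5	30	In	TCRBV25-01	TCRBJ01-03
CSLYIMCFVNYVNVWCRF	12	72	In	TCRBV07-01	TCRBJ01-02
CASR*QETQYF	3	21	Stop	TCRBV23-01	TCRBJ01-01
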