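# Per-case private variant counts from a published WGS case series of
# eight dogs with hyperostotic disorders (CMO/CHS), after filtering
# against 584 population genomes. Cells are count (hom/het).
case_id	total	protein_changing	synonymous	intronic	intergenic
American Staffordshire Terrier (CHS)	4582	76 (67/9)	71 (69/2)	2217 (1832/385)	2218 (1831/387)
Australian Terrier (CMO)	13147	79 (73/6)	30 (24/6)	6527 (6012/515)	6511 (5875/636)
Basset Hound (CMO)	13370	96 (87/9)	30 (28/2)	6535 (5917/618)	6709 (6073/636)
Cairn Terrier (CMO)	7373	55 (45/10)	17 (16/1)	3486 (3066/420)	3815 (3344/471)
Curly Coated Retriever (CMO)	4960	34 (34/0)	15 (15/0)	2405 (2248/157)	2506 (2260/246)
German Wirehaired Pointer (CMO)	11713	63 (52/11)	28 (25/3)	5706 (5137/569)	5916 (5291/625)
Old English Sheepdog (CMO)	10711	59 (52/7)	22 (17/5)	4966 (4175/791)	5664 (4558/1106)
Weimaraner (CMO)	8056	54 (48/6)	26 (21/5)	3859 (3183/676)	4117 (3307/810)
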