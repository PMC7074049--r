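# Default U2-type GT-AG donor splice-site consensus (percent per position).
# Window: -3..-1 exonic, +1..+6 intronic. The +1 G and +2 T anchors are the
# near-invariant canonical dinucleotide (100%); the remaining rows carry
# representative human donor-site frequencies and may be replaced by any
# user-supplied table of the same shape.
position	A	C	G	T
-3	33	37	18	12
-2	60	13	12	15
-1	8	4	81	7
+1	0	0	100	0
+2	0	0	0	100
+3	62	2	33	3
+4	68	9	12	11
+5	8	5	84	3
+6	16	17	19	48
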