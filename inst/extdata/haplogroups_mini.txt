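# Simplified haplogroup tree: diagnostic variants are rCRS-relative.
# Control-region diagnostics follow published motifs; coding diagnostics as
# transcribed for each branch. Scaffold nodes without transcribed
# diagnostics are empty. The literature prints both A16343G and A16344G for
# the U3 basal landmark; 16344 is taken by the M35b2a1 profile (rCRS C), so
# A16343G is canonical and the other spelling is aliased.
#alias A16344G A16343G
rCRS
	M C16223T C10400T T14783C G15043A
		M1 G16129A T16189C T16249C
			M1a1 T16359C
		M5 G16129A
			M5a C16291T
				M5a1a G185A T334C G9064A G11016A
				M5a1b G1303A A6461G
					M5a1b1 C3954T
						M5a1b1a T9833C
							M5a1b1a1 T16298C
		M18 T246C A16318T
		M35
			M35b T16304C
				M35b2a
					M35b2a1 G16129A A16230G C16233T C16344T
	A2 C16111T C16223T C16290T G16319A
	U A12308G
		U3 A16343G
			U3b1c A2833G T7759C T8895C C11119T T12783C T15262C
	H5 T16304C
		H5a2 T152C C16186T C11047T
	H24 A16293G
	H88a T3621C A12712G
	L2 C16223T C16278T G16390A
		L2c C16320T
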