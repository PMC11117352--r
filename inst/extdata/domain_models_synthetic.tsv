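# Synthetic position-specific score model definitions for retroelement
# protein/domain detection.  These are NOT distilled from any curated
# alignment database: they are synthetic stand-in consensus sequences,
# designed so that (a) the bundled synthetic-genome generator embeds them in
# its template ORFs and (b) scoring is fully reproducible offline.  Each row
# defines one model: a consensus string, the per-column consensus emission
# probability (remaining mass uniform over the other 19 residues), the bit
# threshold for reporting a hit, affine gap penalties in bits, and (for INT)
# the 0-based consensus columns of the catalytic D, D and E residues
# (D2->E spacing 35 aa, the canonical integrase geometry).
name	match_prob	bit_threshold	gap_open	gap_extend	cat_d1	cat_d2	cat_e	consensus
RT	0.70	25	8	1	NA	NA	NA	FIRPWGYFPDLPQGSDRHSCSAAYRNRTMATVVMYVDDSLNIDSYWAPCMREEGNWETWC
RH	0.70	25	8	1	NA	NA	NA	PNTTNVVWWHRVQGVWTRSLCWGEHFVCVWTFLGNFVVWT
INT	0.70	25	8	1	2	17	52	DCDEQCTNGTIWQRANWDEMDPHWDAHKHFMVRFLWPARHDLVVVAQCVSDNEIGHSYKF
GAG	0.70	25	8	1	NA	NA	NA	DAYEPKEWFCSYCAACMNKMWVYCHGHLNDEQVVHRWPTWMNFHMGCADG
POL	0.70	25	8	1	NA	NA	NA	VKICCGTIDTGAQKWCLCCECQGWRMMSAQSDVAPQFKIFCHFDVWTERY
ENV	0.70	25	8	1	NA	NA	NA	VHLFSQVWGSNRRLIWTSNMGTHKLFTLESWCESSSPTQHCPWMDFKHYI
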