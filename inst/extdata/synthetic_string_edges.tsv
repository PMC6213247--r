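# SYNTHETIC protein interaction fixture (not a STRING export).
# Constructed edge list emulating the published medium-confidence network
# summary (23 nodes, 52 interactions at confidence >= 0.4) with metabolic
# subnetworks around a transketolase hub; extra sub-threshold edges
# exercise the confidence filter. Database-derived counts depend on the
# database version and are not reproducible from the publication itself.
protein_a	protein_b	evidence	score
Gapdh	Pgk1	functional	0.626
Gapdh	Aldob	physical	0.755
Gapdh	Tpi1	physical	0.93
Gapdh	Pc	functional	0.454
Gapdh	Gk	physical	0.552
Gapdh	Tkt	physical	0.795
Pgk1	Aldob	functional	0.405
Pgk1	Tpi1	physical	0.93
Pgk1	Pc	physical	0.771
Pgk1	Gk	physical	0.461
Pgk1	Tkt	functional	0.507
Aldob	Tpi1	functional	0.787
Aldob	Pc	physical	0.695
Aldob	Gk	physical	0.742
Aldob	Tkt	functional	0.675
Tpi1	Pc	physical	0.735
Tpi1	Gk	physical	0.478
Tpi1	Tkt	functional	0.827
Pc	Gk	physical	0.726
Pc	Tkt	functional	0.46
Gk	Tkt	functional	0.467
Hsd17b10	Acadl	physical	0.929
Hsd17b10	Acaa2	physical	0.516
Hsd17b10	Echs1	physical	0.789
Acadl	Acaa2	functional	0.5
Acadl	Echs1	physical	0.933
Acaa2	Echs1	physical	0.546
Cps1	Otc	functional	0.746
Cps1	Ass1	physical	0.413
Cps1	Glud1	functional	0.847
Cps1	Aldh7a1	physical	0.514
Cps1	Abat	physical	0.816
Otc	Ass1	physical	0.526
Otc	Glud1	functional	0.406
Otc	Aldh7a1	physical	0.781
Otc	Abat	physical	0.561
Ass1	Glud1	physical	0.934
Ass1	Aldh7a1	functional	0.429
Ass1	Abat	physical	0.887
Glud1	Aldh7a1	functional	0.76
Glud1	Abat	physical	0.637
Aldh7a1	Abat	functional	0.856
Glud1	Mdh1	physical	0.816
Glud1	Idh1	physical	0.456
Mdh1	Idh1	physical	0.835
Aldh2	Aldh6a1	functional	0.404
Aldh2	Adh1	functional	0.436
Aldh6a1	Adh1	functional	0.609
Tkt	Mdh1	physical	0.488
Tkt	Glud1	physical	0.91
Tkt	Aldh6a1	physical	0.776
Fah	Glud1	physical	0.63
Tkt	Cat	functional	0.25
Prdx6	Cat	functional	0.3
Gapdh	Actb	physical	0.2
Alb	Fah	functional	0.35
Rgn	Pc	functional	0.15
Tst	Mdh1	functional	0.3
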