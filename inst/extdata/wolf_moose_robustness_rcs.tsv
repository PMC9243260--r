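run	rcs_xy	rcs_yx	acs_xy	acs_yx
1	0.7168	0.2832	0.2237	0.0884
2	0.5374	0.4626	0.1927	0.1659
3	0.6804	0.3196	0.2003	0.0941
4	0.7594	0.2306	0.1810	0.0542
5	0.6364	0.3636	0.2048	0.1170
6	0.6042	0.3958	0.1971	0.1291
7	0.6398	0.3602	0.2038	0.1148
8	0.6585	0.3415	0.1974	0.1024
9	0.5943	0.4057	0.1923	0.1313
10	0.5473	0.4527	0.1979	0.1637
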