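row	echo_comparison	echo_parallel_genes	echo_parallel_sites	echo_convergent_genes	echo_convergent_sites	control_comparison	control_parallel_genes	control_parallel_sites	control_convergent_genes	control_convergent_sites
1	CF vs. FM	154	171	0	0	CF vs. nonecholocating bat	117	124	1	1
2	CF vs. click bat	207	248	3	3	CF vs. nonecholocating bat	117	124	1	1
3	FM vs. click bat	177	203	6	6	FM vs. nonecholocating bat	118	122	2	2
4	CF vs. toothed whale	119	129	11	11	CF vs. nonecholocating whale	84	89	5	5
5	FM vs. toothed whale	94	98	2	2	FM vs. nonecholocating whale	87	92	3	3
6	Click bat vs. toothed whale	96	104	11	11	Click bat vs. nonecholocating whale	90	97	3	3
7	Click bat vs. toothed whale	96	104	11	11	Nonecholocating bat vs. toothed whale	62	65	5	5
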