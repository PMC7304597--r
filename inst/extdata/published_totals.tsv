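genome	n_calls	total_genes	total_no_bp	total_no_go
rice	130	2409	1014	612
arabidopsis	67	1177	472	259
grapevine	142	2594	805	485
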