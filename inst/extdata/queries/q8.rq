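SELECT * WHERE {?gp1 go:consider ?gp2 . ?gp1 ?p1 ?ns1 FILTER regex (?ns1, "cellular") .?gp2 ?p2 ?ns2 FILTER regex (?ns2, "molecular") .}
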