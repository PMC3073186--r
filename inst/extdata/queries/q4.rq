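SELECT * WHERE {?gp rdf:type ?type .?gp rdfs:label ?name FILTER regex (?name, "BP.*mouse") .}
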