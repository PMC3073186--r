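# Locale-independent string sort (C collation via radix order).
c_sort <- function(x) x[order(x, method = "radix")]

# ceiling() to integer pages
pages_of <- function(entries, per_page) as.integer(ceiling(entries / per_page))
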