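logit <- function(p) log(p) - log1p(-p)

expit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# locus key used wherever loci are matched across matrices / tables
locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
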