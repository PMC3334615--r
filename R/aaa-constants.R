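# Shared constants; this file sorts first so top-level code in later files
# can use them at load time.

CLADES <- c("bacteria", "protozoa", "fungi", "plants", "protostomes",
            "deuterostomes")

# 20 standard residues plus ambiguity codes accepted everywhere
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O", "J")
AA_ALPHABET <- c(AA_STANDARD, AA_AMBIGUOUS)

`%||%` <- function(a, b) if (is.null(a)) b else a
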