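# Shared fixture builders. Everything is generated in code; no files.

tinyStudy <- function(seed = 1, nProteins = 40, nGenes = 150, ...) {
    simulateStudy(seed = seed, nProteins = nProteins, nGenes = nGenes, ...)
}

twoGroup22 <- factor(rep(c("control", "high"), each = 2),
                     levels = c("control", "high"))

# one-gene-per-protein map over a truth table
identityMap <- function(truth) {
    data.frame(gene_id = paste0("g.", truth$feature_id),
               protein_id = truth$feature_id,
               stringsAsFactors = FALSE)
}
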