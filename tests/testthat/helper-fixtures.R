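# Small fixtures shared across tests; everything is generated in code.

fastConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(nProbes = 600L, nGenes = 150L, nEffect = 40L, seed = seed),
    list(...))
  do.call(simulationConfig, args)
}

tinyMethylationSet <- function(beta, groups,
                               gene = rep("G1", nrow(beta))) {
  probeInfo <- data.frame(gene = gene, designType = "II",
                          minBeadCount = 10L, hasCpG = TRUE,
                          nearSNP = FALSE, multiMap = FALSE,
                          row.names = rownames(beta))
  MethylationSet(beta, data.frame(group = groups), probeInfo)
}

maePerm2 <- function(omega, truth) {
  min(mean(abs(omega - truth)), mean(abs(omega[, 2:1] - truth)))
}

alignOmega2 <- function(omega, truth) {
  if (mean(abs(omega - truth)) <= mean(abs(omega[, 2:1] - truth))) omega
  else omega[, 2:1]
}
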