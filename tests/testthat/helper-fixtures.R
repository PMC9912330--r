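# minimal CSPTable with prescribed labels/flags, for tests that drive
# downstream stages directly
cspStub <- function(labels, significant = rep(TRUE, length(labels)),
                    ddMax = seq(0.2, 0.4, length.out = length(labels)),
                    overlap = rep(FALSE, length(labels))) {
  n <- length(labels)
  new("CSPTable", label = labels,
      dd = matrix(0, n, 1, dimnames = list(labels, "0")),
      ddMax = ddMax, linearity = rep(0, n), overlap = overlap,
      significant = significant, sigmaC = 0.05,
      sigmaIterations = 1L, sigmaExcluded = character(),
      saturatedStep = 0L, saturationDiagnostic = 0, nWeight = 0.14)
}
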