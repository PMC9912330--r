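# Independent oracles used to validate the analytical implementations.

# Bound fraction from the mass-action equilibrium solved numerically:
# with [P] scaled to 1, f solves betaD * f = (1 - f) * (alpha - f) on
# [0, min(1, alpha)]. Deliberately avoids the closed-form quadratic.
massActionF <- function(alpha, betaD) {
  if (alpha == 0) return(0)
  g <- function(f) betaD * f - (1 - f) * (alpha - f)
  hi <- min(1, alpha)
  stats::uniroot(g, c(0, hi), tol = 1e-14)$root
}

# Exhaustive check of the corrected-standard-deviation iteration:
# explore every order of single-value exclusions (any value exceeding
# k * sigma of the current retained set may be removed next) and
# collect the terminal sigma of every path. For the iteration to be
# well-defined all paths must agree.
sigmaCAllOrders <- function(values, k = 3) {
  sdZero <- function(v) sqrt(mean(v^2))
  recurse <- function(keep) {
    s <- sdZero(values[keep])
    cand <- which(keep & values > k * s)
    if (!length(cand)) return(s)
    unlist(lapply(cand, function(i) {
      nxt <- keep
      nxt[i] <- FALSE
      recurse(nxt)
    }))
  }
  unique(signif(recurse(rep(TRUE, length(values))), 12))
}

# fixed-width PDB ATOM record for synthetic structure fixtures
pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                        occ = 1, b = 0, elem = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resn, chain, resno, x, y, z, occ, b, elem)
}

# minimal synthetic three-residue PDB (backbone N/CA only)
writeTinyPdb <- function(path, resnos = c(96, 97, 98),
                         resns = c("ARG", "THR", "GLU")) {
  lines <- c("HEADER    SYNTHETIC TEST STRUCTURE")
  serial <- 0L
  for (i in seq_along(resnos)) {
    for (atom in c("N", "CA")) {
      serial <- serial + 1L
      lines <- c(lines, pdbAtomLine(serial, atom, resns[i], "A",
                                    resnos[i], i * 3.8, 0, 0))
    }
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  path
}
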