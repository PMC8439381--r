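#' Read SEQRES one-letter sequences from a PDB file
#'
#' @param path PDB file path.
#' @return named character vector, one sequence string per chain.
#' @export
read_seqres <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sq <- lines[startsWith(lines, "SEQRES")]
  if (!length(sq)) stop("no SEQRES records in ", path)
  three_to_one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
                    MSE = "M", HIE = "H", HID = "H", HIP = "H")
  chains <- substr(sq, 12, 12)
  out <- vapply(unique(chains), function(ch) {
    toks <- unlist(strsplit(trimws(substr(sq[chains == ch], 20, 70)), "\\s+"))
    aa <- three_to_one[toupper(toks)]
    paste(ifelse(is.na(aa), "X", aa), collapse = "")
  }, character(1))
  names(out) <- unique(chains)
  out
}

#' Global pairwise sequence identity (Needleman-Wunsch)
#'
#' Simple global alignment with match/mismatch/gap scoring; identity is the
#' fraction of aligned (non-gap) columns with identical residues, in
#' percent.
#'
#' @param a,b sequence strings.
#' @param match,mismatch,gap scoring parameters.
#' @return list: `identity` (percent), `n_aligned`, `n_identical`,
#'   `alignment` (two gapped strings).
#' @export
sequence_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  s1 <- strsplit(a, "")[[1]]; s2 <- strsplit(b, "")[[1]]
  n <- length(s1); m <- length(s2)
  if (!n || !m) stop("empty sequence")
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(s2 == s1[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  # traceback
  i <- n; j <- m; g1 <- character(0); g2 <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(s1[i] == s2[j], match, mismatch)) {
      g1 <- c(s1[i], g1); g2 <- c(s2[j], g2); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      g1 <- c(s1[i], g1); g2 <- c("-", g2); i <- i - 1
    } else {
      g1 <- c("-", g1); g2 <- c(s2[j], g2); j <- j - 1
    }
  }
  aligned <- g1 != "-" & g2 != "-"
  ident <- sum(g1 == g2 & aligned)
  list(identity = 100 * ident / sum(aligned),
       n_aligned = sum(aligned), n_identical = ident,
       alignment = c(paste(g1, collapse = ""), paste(g2, collapse = "")))
}
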