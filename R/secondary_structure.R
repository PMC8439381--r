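#' Reconstruct backbone amide hydrogens
#'
#' For residues lacking an explicit amide H (crystal inputs), the hydrogen
#' is placed 1.01 A from N opposite the preceding residue's C=O direction
#' (along the unit vector from O(i-1) to C(i-1)), the classic geometric
#' reconstruction used by secondary-structure assignment. The first residue
#' of a chain gets no reconstructed H.
#'
#' @param frame coordinates (n_atoms x 3).
#' @param top matching `topology`.
#' @param chain chain id (default: first chain present).
#' @return list: `h` matrix (n_res x 3, NA where unavailable), `residues`
#'   data.frame with backbone atom indices (`n`,`ca`,`c`,`o`,`h_explicit`).
#' @export
reconstruct_amide_h <- function(frame, top, chain = NULL) {
  bb <- .backbone_table(top, chain)
  n_res <- nrow(bb)
  H <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    if (!is.na(bb$h_explicit[i])) { H[i, ] <- frame[bb$h_explicit[i], ]; next }
    if (i == 1L || is.na(bb$c[i - 1]) || is.na(bb$o[i - 1]) || is.na(bb$n[i])) next
    dir <- .unit(frame[bb$c[i - 1], ] - frame[bb$o[i - 1], ])
    H[i, ] <- frame[bb$n[i], ] + 1.01 * dir
  }
  list(h = H, residues = bb)
}

# backbone atom index table per residue of a chain (NA where missing)
.backbone_table <- function(top, chain = NULL) {
  a <- top$atoms
  prot <- toupper(a$resname) %in% .STANDARD_AA
  if (is.null(chain)) chain <- a$chain[prot][1]
  rows <- which(prot & a$chain == chain)
  if (!length(rows)) stop("no protein residues in chain '", chain, "'")
  resids <- sort(unique(a$resid[rows]))
  find1 <- function(rid, nm) {
    w <- rows[a$resid[rows] == rid & a$name %in% nm]
    if (length(w)) w[1] else NA_integer_
  }
  data.frame(
    resid = resids,
    resname = vapply(resids, function(r) a$resname[rows[a$resid[rows] == r][1]], ""),
    n = vapply(resids, find1, 0L, nm = "N"),
    ca = vapply(resids, find1, 0L, nm = "CA"),
    c = vapply(resids, find1, 0L, nm = "C"),
    o = vapply(resids, find1, 0L, nm = "O"),
    h_explicit = vapply(resids, find1, 0L, nm = c("H", "HN")),
    stringsAsFactors = FALSE)
}

# Kabsch-Sander backbone H-bond energy matrix: entry [d, a] = TRUE when the
# N-H of residue d donates to the C=O of residue a (E < -0.5 kcal/mol).
.ks_hbond_matrix <- function(frame, top, chain = NULL, e_cutoff = -0.5) {
  rec <- reconstruct_amide_h(frame, top, chain)
  bb <- rec$residues; H <- rec$h
  n_res <- nrow(bb)
  hb <- matrix(FALSE, n_res, n_res)
  q <- 0.084 * 332  # kcal/mol with distances in A
  for (d in seq_len(n_res)) {
    if (is.na(bb$n[d]) || anyNA(H[d, ])) next
    if (toupper(bb$resname[d]) == "PRO") next  # no amide H
    Nd <- frame[bb$n[d], ]; Hd <- H[d, ]
    for (a in seq_len(n_res)) {
      if (a == d || a == d - 1L) next  # covalently linked peptide unit
      if (is.na(bb$c[a]) || is.na(bb$o[a])) next
      Ca <- frame[bb$c[a], ]; Oa <- frame[bb$o[a], ]
      rON <- .vnorm(Oa - Nd); rCH <- .vnorm(Ca - Hd)
      rOH <- .vnorm(Oa - Hd); rCN <- .vnorm(Ca - Nd)
      if (min(rON, rCH, rOH, rCN) < 0.5) next
      e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[d, a] <- e < e_cutoff
    }
  }
  list(hb = hb, residues = bb)
}

#' Kabsch-Sander secondary-structure assignment for one frame
#'
#' Backbone hydrogen bonds are identified with the electrostatic criterion
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) < -0.5 kcal/mol`
#' (amide H reconstructed when absent), then pattern-matched: n-turns give
#' G/H/I (3/4/5-turn helices), bridges give E (ladders) or B (isolated),
#' turns T, bends S (Calpha kappa angle > 70 deg), else C. Assignment
#' priority: H > E > B > G > I > T > S. Residues missing backbone atoms are
#' flagged with NA.
#'
#' @param frame coordinates (n_atoms x 3).
#' @param top matching `topology`.
#' @param chain chain id (default: first protein chain).
#' @return character vector of per-residue codes, names = residue numbers;
#'   attribute `residues` holds the backbone table.
#' @export
assign_secondary_structure <- function(frame, top, chain = NULL) {
  ks <- .ks_hbond_matrix(frame, top, chain)
  hb <- ks$hb; bb <- ks$residues
  n_res <- nrow(bb)
  missing_bb <- is.na(bb$n) | is.na(bb$ca) | is.na(bb$c) | is.na(bb$o)
  code <- rep("C", n_res)
  if (n_res < 5L) {
    code[missing_bb] <- NA_character_
    names(code) <- bb$resid
    attr(code, "residues") <- bb
    return(code)
  }

  turn_at <- function(n) {
    t <- rep(FALSE, n_res)
    for (i in seq_len(n_res - n)) t[i] <- hb[i + n, i]
    t
  }
  t3 <- turn_at(3L); t4 <- turn_at(4L); t5 <- turn_at(5L)

  mark <- function(code, idx, ch) {
    free <- code[idx] == "C"
    code[idx[free]] <- ch
    code
  }
  # helices: two consecutive n-turns
  for (i in 2:max(2, n_res)) {
    if (i <= n_res - 4L && t4[i - 1] && t4[i]) code[i:(i + 3)] <- "H"
  }
  # bridges (Kabsch-Sander parallel/antiparallel patterns), |i-j| > 2
  bridge <- matrix(FALSE, n_res, n_res)
  safe_hb <- function(d, a) d >= 1 && d <= n_res && a >= 1 && a <= n_res && hb[d, a]
  for (i in 2:(n_res - 1)) {
    for (j in 2:(n_res - 1)) {
      if (abs(i - j) <= 2) next
      par <- (safe_hb(j, i - 1) && safe_hb(i + 1, j)) ||
             (safe_hb(i, j - 1) && safe_hb(j + 1, i))
      anti <- (safe_hb(j, i) && safe_hb(i, j)) ||
              (safe_hb(j + 1, i - 1) && safe_hb(i + 1, j - 1))
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  is_bridge <- apply(bridge, 1, any)
  if (any(is_bridge)) {
    # ladders: bridge residues with a sequence-adjacent bridge residue -> E
    ladder <- is_bridge & (c(FALSE, is_bridge[-n_res]) | c(is_bridge[-1], FALSE))
    for (i in which(is_bridge)) {
      if (code[i] == "H") next  # priority H > E
      code[i] <- if (ladder[i]) "E" else "B"
    }
  }
  # 3-10 and pi helices on residues still unassigned
  for (i in 2:max(2, n_res)) {
    if (i <= n_res - 3L && t3[i - 1] && t3[i]) code <- mark(code, i:(i + 2), "G")
  }
  for (i in 2:max(2, n_res)) {
    if (i <= n_res - 5L && t5[i - 1] && t5[i]) code <- mark(code, i:(i + 4), "I")
  }
  # turns: interior residues of any single n-turn
  for (n in c(3L, 4L, 5L)) {
    t <- switch(as.character(n), "3" = t3, "4" = t4, "5" = t5)
    for (i in which(t)) {
      span <- (i + 1):(i + n - 1)
      span <- span[span <= n_res]
      code <- mark(code, span, "T")
    }
  }
  # bends: kappa(CA[i-2], CA[i], CA[i+2]) > 70 deg
  for (i in 3:max(3, n_res - 2)) {
    if (code[i] != "C") next
    ii <- c(bb$ca[i - 2], bb$ca[i], bb$ca[i + 2])
    if (anyNA(ii)) next
    u <- frame[ii[2], ] - frame[ii[1], ]; v <- frame[ii[3], ] - frame[ii[2], ]
    kappa <- acos(pmin(1, pmax(-1, sum(u * v) / (.vnorm(u) * .vnorm(v))))) * 180 / pi
    if (kappa > 70) code[i] <- "S"
  }
  code[missing_bb] <- NA_character_
  # chain termini are never H/E
  if (!is.na(code[1]) && code[1] %in% c("H", "E")) code[1] <- "C"
  if (!is.na(code[n_res]) && code[n_res] %in% c("H", "E")) code[n_res] <- "C"
  names(code) <- bb$resid
  attr(code, "residues") <- bb
  code
}

#' Secondary-structure timeline over an ensemble
#'
#' @param ens an `ensemble`.
#' @param top matching `topology`.
#' @param chain chain id.
#' @return list: `matrix` (residues x frames codes), `fractions`
#'   (data.frame, % of frames per code per residue, rows sum to 100).
#' @export
ss_timeline <- function(ens, top, chain = NULL) {
  nfr <- n_frames(ens)
  first <- assign_secondary_structure(frame_coords(ens, 1), top, chain)
  m <- matrix(NA_character_, nrow = length(first), ncol = nfr,
              dimnames = list(names(first), NULL))
  m[, 1] <- first
  if (nfr > 1) for (f in 2:nfr) {
    m[, f] <- assign_secondary_structure(frame_coords(ens, f), top, chain)
  }
  codes <- c("H", "G", "I", "E", "B", "T", "S", "C")
  frac <- t(apply(m, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(stats::setNames(rep(NA_real_, length(codes)), codes))
    100 * vapply(codes, function(cc) mean(row == cc), numeric(1))
  }))
  frac <- data.frame(resid = as.integer(rownames(m)), frac,
                     check.names = FALSE)
  list(matrix = m, fractions = frac)
}

#' Write per-frame secondary-structure strings (one row per frame)
#' @param ssm result of [ss_timeline()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ss_timeline <- function(ssm, path) {
  m <- ssm$matrix
  lines <- apply(m, 2, function(col) paste(ifelse(is.na(col), "!", col),
                                           collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
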