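#' Assign secondary structure from backbone geometry
#'
#' Kabsch-Sander style assignment from backbone hydrogen bonds. The amide
#' hydrogen is placed on the N-H direction anti-parallel to the preceding
#' C=O bond; the bond energy is the standard electrostatic approximation
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol and a bond
#' is called when E < -0.5 kcal/mol. Two consecutive i -> i+4 turns define a
#' helix (H); bridge patterns between strands define sheet (E); remaining
#' turn (3/4/5-turn interior) and bend (CA virtual angle > 70 degrees)
#' residues are labelled `other`; everything else is coil (C). The
#' four states are mutually exclusive, so alpha + beta + coil can be less
#' than the chain length.
#'
#' @param model A [structure_model][parse_structure] with backbone N, CA, C
#'   (and O for acceptors) atoms.
#' @return Character vector, one label per residue, over `{H, E, C, other}`.
#' @export
assign_secondary_structure <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  n <- nrow(model$residues)
  bb <- backbone_coords(model)
  complete <- stats::complete.cases(bb$N) & stats::complete.cases(bb$CA) &
    stats::complete.cases(bb$C)
  if (mean(!complete) > 0.2)
    stop(sprintf("missing backbone atoms in %d of %d residues (> 20%%)",
                 sum(!complete), n), call. = FALSE)
  if (sum(complete) < 5L)
    stop("need at least 5 residues with complete backbone", call. = FALSE)

  hb <- hbond_matrix(model, bb, complete)

  lab <- rep("C", n)

  # n-turns: turn[[k]][i] TRUE when CO(i) bonds NH(i+k)
  turn <- lapply(3:5, function(k) {
    t <- rep(FALSE, n)
    idx <- seq_len(n - k)
    t[idx] <- hb[cbind(idx + k, idx)]
    t
  })
  names(turn) <- c("t3", "t4", "t5")

  # helix: 4-turns at i-1 and i cover residues i..i+3
  if (n >= 6) {
    for (i in 2:(n - 4)) {
      if (turn$t4[i - 1] && turn$t4[i]) lab[i:(i + 3)] <- "H"
    }
  }

  # bridges (parallel / antiparallel), Hbond(a, b) = CO(a) to NH(b) = hb[b, a]
  isE <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      par <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[j, i] && hb[i, j]) ||
        (j + 1 <= n && i + 1 <= n && hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par || anti) { isE[i] <- TRUE; isE[j] <- TRUE }
    }
  }
  lab[isE & lab != "H"] <- "E"

  # turn interiors
  for (k in 3:5) {
    tk <- turn[[k - 2]]
    for (i in which(tk)) {
      span <- (i + 1):(i + k - 1)
      span <- span[span <= n]
      lab[span][lab[span] == "C"] <- "other"
    }
  }

  # bend: virtual-bond angle at CA(i)
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      if (!all(complete[c(i - 2, i, i + 2)])) next
      v1 <- bb$CA[i, ] - bb$CA[i - 2, ]
      v2 <- bb$CA[i + 2, ] - bb$CA[i, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      if (acos(pmin(1, pmax(-1, cosang))) > 70 * pi / 180 && lab[i] == "C")
        lab[i] <- "other"
    }
  }
  lab
}

# per-residue backbone coordinate matrices (NA rows when atom missing)
backbone_coords <- function(model) {
  n <- nrow(model$residues)
  pick <- function(name) {
    m <- matrix(NA_real_, n, 3)
    sel <- model$atoms$name == name
    m[model$atoms$residue[sel], ] <-
      as.matrix(model$atoms[sel, c("x", "y", "z")])
    m
  }
  list(N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"))
}

# hb[i, j]: N-H of residue i donates to C=O of residue j
hbond_matrix <- function(model, bb, complete) {
  n <- nrow(model$residues)
  hb <- matrix(FALSE, n, n)
  # amide H: on N, anti-parallel to previous C=O
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (!complete[i] || !complete[i - 1]) next
    co <- bb$C[i - 1, ] - bb$O[i - 1, ]
    d <- sqrt(sum(co^2))
    if (!is.finite(d) || d == 0) next
    H[i, ] <- bb$N[i, ] + co / d
  }
  q <- 0.084 * 332
  for (i in 2:n) {                      # donor (residue 1 and Pro cannot donate)
    if (any(is.na(H[i, ])) || model$residues$aa[i] == "P") next
    for (j in seq_len(n)) {             # acceptor
      if (abs(i - j) < 2) next
      if (!complete[j] || any(is.na(bb$O[j, ]))) next
      r_on <- sqrt(sum((bb$O[j, ] - bb$N[i, ])^2))
      if (r_on > 5.2) next              # distance prefilter
      r_ch <- sqrt(sum((bb$C[j, ] - H[i, ])^2))
      r_oh <- sqrt(sum((bb$O[j, ] - H[i, ])^2))
      r_cn <- sqrt(sum((bb$C[j, ] - bb$N[i, ])^2))
      e <- q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      if (e < -0.5) hb[i, j] <- TRUE
    }
  }
  hb
}
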