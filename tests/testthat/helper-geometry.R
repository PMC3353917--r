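# Analytic peptide construction from internal coordinates, used to build
# secondary-structure fixtures, plus PDB text formatting and an independent
# Monte-Carlo SASA oracle.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place atom D bonded to C: |CD| = r, angle(B,C,D) = theta, dihedral(A,B,C,D) = chi
place_atom <- function(a, b, c, r, theta, chi) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi), r * sin(theta) * sin(chi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

deg <- function(x) x * pi / 180

# ideal-geometry backbone (N, CA, C, O) for given phi/psi, omega = 180
build_peptide <- function(n, phi, psi, aa = "ALA") {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- deg(111.2); a_cacn <- deg(116.2); a_cnca <- deg(121.7)
  a_caco <- deg(120.8)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_nca, 0, 0)
  C[1, ] <- CA[1, ] + b_cac * c(-cos(a_ncac), sin(a_ncac), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           b_cn, a_cacn, deg(psi[i - 1]))
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            b_nca, a_cnca, deg(180))
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           b_cac, a_ncac, deg(phi[i]))
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_co, a_caco,
                         deg(psi[i] - 180))
  }
  list(N = N, CA = CA, C = C, O = O, resid = rep(aa, n))
}

# fixed-column PDB ATOM records for one or more peptide objects
peptide_pdb_text <- function(..., chain = "A") {
  peps <- list(...)
  lines <- character(0)
  serial <- 0L; resno <- 0L
  for (p in peps) {
    for (i in seq_len(nrow(p$N))) {
      resno <- resno + 1L
      for (at in c("N", "CA", "C", "O")) {
        serial <- serial + 1L
        xyz <- p[[at]][i, ]
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, at, p$resid[i], chain, resno, xyz[1], xyz[2], xyz[3],
          substr(at, 1, 1)))
      }
    }
  }
  c(lines, "END")
}

# independent SASA oracle: uniform Monte-Carlo points on each expanded sphere
brute_sasa <- function(xyz, radii, probe = 1.4, n_mc = 20000, seed = 42) {
  set.seed(seed)
  n <- nrow(xyz)
  er <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    z <- runif(n_mc, -1, 1)
    th <- runif(n_mc, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    pts <- cbind(xyz[i, 1] + er[i] * r * cos(th),
                 xyz[i, 2] + er[i] * r * sin(th),
                 xyz[i, 3] + er[i] * z)
    free <- rep(TRUE, n_mc)
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= er[j]^2
    }
    areas[i] <- 4 * pi * er[i]^2 * mean(free)
  }
  areas
}

# single-chain structure_model straight from coordinate matrices
model_from_peptide <- function(pep, chain = "A") {
  parse_structure(peptide_pdb_text(pep, chain = chain), chain = chain)
}

# two antiparallel extended strands: the partner strand is superposed
# (Kabsch fit) onto ideal hydrogen-bond target points built from the first
# strand's N-H and C=O directions (narrow pairs i = 2,4,6 <-> j = 9-i)
build_antiparallel_sheet <- function() {
  s1 <- build_peptide(8, -139, 135)
  hpos <- function(p, i) {
    co <- p$C[i - 1, ] - p$O[i - 1, ]
    p$N[i, ] + co / sqrt(sum(co^2))
  }
  unitv <- function(v) v / sqrt(sum(v^2))
  tgt <- NULL; src <- NULL
  for (i in c(2, 4, 6)) {
    j <- 9 - i
    nh <- unitv(hpos(s1, i) - s1$N[i, ])
    co <- unitv(s1$O[i, ] - s1$C[i, ])
    tgt <- rbind(tgt, s1$N[i, ] + 2.95 * nh, s1$O[i, ] + 2.95 * co)
    src <- rbind(src, s1$O[j, ], s1$N[j, ])
  }
  cs <- colMeans(src); ct <- colMeans(tgt)
  H <- t(src - matrix(cs, nrow(src), 3, byrow = TRUE)) %*%
    (tgt - matrix(ct, nrow(tgt), 3, byrow = TRUE))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  s2 <- s1
  for (at in c("N", "CA", "C", "O"))
    s2[[at]] <- t(R %*% (t(s1[[at]]) - cs)) + matrix(ct, 8, 3, byrow = TRUE)
  list(s1 = s1, s2 = s2)
}

# direct access to the sphere-point area kernel for property tests
sasa_points_per_atom <- function(xyz, radii, probe = 1.4, n_points = 2000) {
  randnat:::sasa_shrake_rupley_cpp(xyz, radii, probe, as.integer(n_points))
}
sasa_points_total <- function(xyz, radii, probe = 1.4, n_points = 2000) {
  sum(sasa_points_per_atom(xyz, radii, probe, n_points))
}
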