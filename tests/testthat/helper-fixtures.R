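# shared fixtures, built once per test run

ring_c4 <- build_ring(ring_spec(n = 4, layers = 1, ring_radius = 45,
                                bend_angle = 110, adjacent_angle = 52))
ring_d3 <- build_ring(ring_spec(n = 3, layers = 2, ring_radius = 45,
                                bend_angle = 110, adjacent_angle = 52))

cpc_buffer <- hydro_params(rho = 1.00980, eta = 0.01029, vbar = 0.73149,
                           temperature = 293.15, rotor_rpm = 60000)
water20 <- hydro_params(rho = 0.998234, eta = 0.010020, vbar = 0.73149)

# random proper rotation + translation, applied to a whole assembly
random_rigid <- function(assembly, seed = 42) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tvec <- rnorm(3, sd = 20)
  xyz <- as.matrix(assembly$atoms[, c("x", "y", "z")]) %*% t(R)
  assembly$atoms$x <- xyz[, 1] + tvec[1]
  assembly$atoms$y <- xyz[, 2] + tvec[2]
  assembly$atoms$z <- xyz[, 3] + tvec[3]
  assembly
}

# analytic accessible area of two identical expanded spheres of radius R at
# centre distance d: per-sphere buried cap area = 2*pi*R*h, h = R - d/2
two_sphere_cap_area <- function(R, d) 2 * pi * R * (R - d / 2)

# independent brute-force global alignment score (match +1, mismatch 0,
# gap -1) by plain recursion with memoisation on sequence suffixes
brute_align_score <- function(s1, s2) {
  memo <- new.env()
  go <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i > length(s1)) -(length(s2) - j + 1) else
      if (j > length(s2)) -(length(s1) - i + 1) else
        max(ifelse(s1[i] == s2[j], 1, 0) + go(i + 1, j + 1),
            -1 + go(i + 1, j),
            -1 + go(i, j + 1))
    memo[[key]] <- val
    val
  }
  go(1, 1)
}

# tiny two-chain C-alpha assembly with prescribed residue numbers
toy_two_chain <- function(resno_a, resno_b, seq_a = NULL, seq_b = NULL) {
  mk <- function(resno, chain, resid, x0) {
    data.frame(element = "C", name = "CA",
               resid = if (is.null(resid)) "ALA" else resid,
               resno = resno, chain = chain,
               x = x0 + seq_along(resno) * 3.8,
               y = rep(0, length(resno)), z = rep(0.5, length(resno)) * seq_along(resno) %% 3,
               hetero = FALSE, occ = 1, b = 0, stringsAsFactors = FALSE)
  }
  assembly(rbind(mk(resno_a, "A", seq_a, 0), mk(resno_b, "B", seq_b, 1)))
}
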