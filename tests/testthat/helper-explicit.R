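# Independent brute-force reference integrator: fully explicit Euler for
# reactions, transfers and diffusion, with its own masked 5-point Laplacian
# and its own transcription of the rate laws. Deliberately does not call the
# package's kinetics/transport/solver routines, so it can serve as an
# oracle for the semi-implicit engine.
explicit_reference_run <- function(state, domain, params, dt, n_steps,
                                   ec_first_order = FALSE) {
  f <- state$fields
  p <- params
  mask <- domain$mask
  h <- domain$h
  nx <- domain$nx
  ny <- domain$ny
  comp_of <- c(G_c = 1, F_c = 1, C_c = 1, Xi_c = 1, P_c = 1, Ups_c = 1,
               Theta_c = 1, E_c = 1,
               G_n = 2, C_n = 2, Xi_n = 2, P_n = 2, Ups_n = 2)
  shift <- function(m, di, dj) {
    out <- matrix(0, nx, ny)
    si <- seq_len(nx); sj <- seq_len(ny)
    ii <- si + di; jj <- sj + dj
    ok_i <- ii >= 1 & ii <= nx; ok_j <- jj >= 1 & jj <= ny
    out[si[ok_i], sj[ok_j]] <- m[ii[ok_i], jj[ok_j]]
    out
  }
  lap <- function(u, comp) {
    inb <- mask == comp
    u0 <- u * inb
    tot <- matrix(0, nx, ny); deg <- matrix(0, nx, ny)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- shift(inb, d[1], d[2])
      tot <- tot + shift(u0, d[1], d[2]) * nb
      deg <- deg + nb
    }
    (tot - deg * u0) * inb
  }
  faces <- domain$nuclear_faces
  cyt <- mask == 1; nuc <- mask == 2
  for (s in seq_len(n_steps)) {
    G <- f$G_c; Fa <- f$F_c; C <- f$C_c; Xi <- f$Xi_c; P <- f$P_c
    U <- f$Ups_c; Th <- f$Theta_c; E <- f$E_c
    Gn <- f$G_n; Cn <- f$C_n; Xin <- f$Xi_n; Pn <- f$P_n; Un <- f$Ups_n
    pol <- p$gamma_Gc * (1 + p$mu1 * E) * G
    dep <- p$gamma_Fc * Fa
    aXi <- p$alpha_Xi_c * G * C;  dXi <- p$gamma_Xi_c * Xi
    aU  <- p$alpha_Ups_c * G * P; dU  <- p$gamma_Ups_c * U
    ph  <- p$alpha_Theta_c * (1 + p$mu2 * E) * C
    deph <- p$gamma_Theta_c * Th
    aXin <- p$alpha_Xi_n * Gn * Cn;  dXin <- p$gamma_Xi_n * Xin
    aUn  <- p$alpha_Ups_n * Gn * Pn; dUn  <- p$gamma_Ups_n * Un
    d <- list(
      G_c = dep - pol + dXi - aXi + dU - aU, F_c = pol - dep,
      C_c = dXi - aXi - ph + deph, Xi_c = aXi - dXi,
      P_c = dU - aU, Ups_c = aU - dU, Theta_c = ph - deph,
      E_c = if (ec_first_order) -p$gamma_Ec * E
            else matrix(-p$gamma_Ec, nx, ny),
      G_n = dXin - aXin + dUn - aUn, C_n = dXin - aXin, Xi_n = aXin - dXin,
      P_n = dUn - aUn, Ups_n = aUn - dUn)
    for (nm in names(d)) {
      inb <- if (comp_of[[nm]] == 1) cyt else nuc
      f[[nm]] <- f[[nm]] + dt * d[[nm]] * inb
    }
    tr <- function(cn, nn, flux) {
      dc <- flux * dt / h
      # aggregate per cell: a stair-step boundary cell can carry several faces
      ac <- rowsum(dc, faces$cyt); an <- rowsum(dc, faces$nuc)
      ic <- as.integer(rownames(ac)); im <- as.integer(rownames(an))
      f[[cn]][ic] <<- f[[cn]][ic] - as.numeric(ac)
      f[[nn]][im] <<- f[[nn]][im] + as.numeric(an)
    }
    tr("P_c", "P_n",
       p$beta_Pc * f$P_c[faces$cyt] - p$beta_Pn * f$P_n[faces$nuc])
    tr("C_c", "C_n",
       p$beta_Cc * f$C_c[faces$cyt] - p$beta_Cn * f$C_n[faces$nuc])
    tr("Xi_c", "Xi_n", p$beta_Xi_c * f$Xi_c[faces$cyt])
    tr("Ups_c", "Ups_n", -p$beta_Ups_n * f$Ups_n[faces$nuc])
    a <- p$D * dt / h^2
    for (nm in names(f)) {
      if (a[[nm]] > 0) f[[nm]] <- f[[nm]] + a[[nm]] * lap(f[[nm]], comp_of[[nm]])
    }
  }
  structure(list(fields = f, t = state$t + n_steps * dt),
            class = "field_state")
}
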