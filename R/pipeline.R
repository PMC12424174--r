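# High-level driver: monomer method specifications, monomer solutions, and
# the first-order interaction energy pipeline.

#' Monomer method specification
#'
#' @param kind One of `"hf"`, `"fci"`, `"cas"`, `"gvb"` (`gvb` is
#'   `cas` with two active orbitals: one perfect-pairing geminal).
#' @param ncas Active orbital count for `cas`.
#' @param core Number of doubly occupied core orbitals below the active
#'   space (CAS) .
#' @param frozen Number of frozen-core orbitals excluded from the
#'   wave function and from all exchange sums (index-range restriction);
#'   for `"fci"` this freezes the lowest RHF orbitals, for `"hf"` it
#'   restricts the RDM support to the valence occupied orbitals.
#' @param sym_plane,sym_char Optional symmetry targeting of the CI root: a
#'   mirror plane (`"x"`, `"y"`, `"z"`) and the desired character (+1/-1).
#' @param root Root index within the symmetry-filtered set.
#' @param trunc Relative geminal-coefficient threshold below which FCI
#'   natural orbitals are dropped from the RDM support (their density
#'   weight is the square of the coefficient; the default keeps every
#'   orbital contributing above the numerical noise floor of the energies).
#' @return A `method_spec` object.
#' @export
method_spec <- function(kind = c("hf", "fci", "cas", "gvb"), ncas = NULL,
                        core = 0L, frozen = 0L, sym_plane = NULL,
                        sym_char = NULL, root = 1L, trunc = 1e-7) {
  kind <- match.arg(kind)
  if (kind == "gvb") { kind <- "cas"; ncas <- 2L }
  if (kind == "cas" && is.null(ncas)) stop("cas requires ncas")
  structure(list(kind = kind, ncas = ncas, core = as.integer(core),
                 frozen = as.integer(frozen), sym_plane = sym_plane,
                 sym_char = sym_char, root = root, trunc = trunc),
            class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  lbl <- switch(x$kind,
                hf = "HF",
                fci = if (x$frozen) sprintf("FCI(fc:%d)", x$frozen) else "FCI",
                cas = sprintf("CAS(2,%d)%s", x$ncas,
                              if (x$core) sprintf("+%dcore", x$core) else ""))
  if (!is.null(x$sym_char))
    lbl <- paste0(lbl, sprintf(" [%s-character %+d root]", x$sym_plane, x$sym_char))
  cat(lbl, "\n")
  invisible(x)
}

#' Solve a monomer in the dimer-centered basis
#'
#' Produces the monomer orbitals, the structured geminal-product
#' description used by the exchange fast path, and (optionally) dense
#' RDMs.  All wave functions are expanded in the full dimer basis (ghost
#' functions on the partner monomer).
#'
#' @param sys A [build_dimer_system()] handle.
#' @param monomer `"A"` or `"B"`.
#' @param spec A [method_spec()].
#' @param C0 Optional starting orbitals (warm start along scans).
#' @return A `monomer_state`: support coefficients `C` (spherical AO x
#'   n_support), electron count `N` entering the modified potential,
#'   `struct` ([gem_struct()]), `energy`, and solver metadata.
#' @export
solve_monomer <- function(sys, monomer, spec, C0 = NULL) {
  nel <- if (monomer == "A") sys$nelec_A else sys$nelec_B
  symop <- if (!is.null(spec$sym_plane)) reflection_operator(sys, spec$sym_plane)
  out <- switch(spec$kind,
    hf = {
      hf <- rhf(sys, monomer, C0 = C0)
      nocc <- hf$nocc
      keep <- setdiff(seq_len(nocc), seq_len(spec$frozen))
      Cs <- hf$C[, keep, drop = FALSE]
      groups <- lapply(seq_along(keep), function(i)
        list(orbs = i, g = matrix(1, 1, 1)))
      Dcore <- if (spec$frozen > 0L) {
        Cc <- hf$C[, seq_len(spec$frozen), drop = FALSE]
        2 * Cc %*% t(Cc)
      }
      list(C = Cs, N = 2L * length(keep), Dcore = Dcore,
           struct = gem_struct(groups, length(keep)),
           energy = hf$E, label = if (spec$frozen) sprintf("HF(fc:%d)", spec$frozen) else "HF",
           C_full = hf$C)
    },
    fci = {
      if (nel == 2L && spec$frozen == 0L) {
        Chf <- if (is.null(C0)) rhf(sys, monomer)$C else {
          M <- t(C0) %*% sys$S %*% C0
          C0 %*% solve(chol(M))
        }
        nr <- if (!is.null(spec$sym_char)) 5L else spec$root
        repeat {
          f <- fci2(sys, monomer, C = Chf, nroots = nr, symop = symop)
          sel <- seq_along(f$energies)
          if (!is.null(spec$sym_char))
            sel <- sel[abs(f$characters[sel] - spec$sym_char) < 0.5]
          if (length(sel) >= spec$root) break
          nr <- nr + 6L
          if (nr > 30L) stop("requested FCI root not found")
        }
        pick <- sel[spec$root]
        nat <- gem_natural(f$gmats[[pick]])
        # drop natural orbitals with negligible geminal weight: they carry
        # no density and their contribution to every expectation value is
        # bounded by the dropped coefficient times overlap factors
        keep <- which(abs(nat$coef) > spec$trunc * max(abs(nat$coef)))
        cf <- nat$coef[keep]
        cf <- cf / sqrt(sum(cf^2))
        Cs <- Chf %*% nat$U[, keep, drop = FALSE]
        n <- length(keep)
        list(C = Cs, N = 2L,
             struct = gem_struct(list(list(orbs = seq_len(n),
                                           g = diag(cf, n, n))), n),
             energy = f$energies[pick], label = "FCI",
             character = f$characters[pick], C_full = Chf %*% nat$U)
      } else if (nel == 2L * spec$frozen + 2L) {
        # frozen-core FCI: core = lowest RHF orbitals, CI of the two
        # valence electrons in all remaining orbitals; index-range
        # restriction: the support excludes the core entirely.
        hf <- rhf(sys, monomer, C0 = C0)
        Chf <- hf$C
        icore <- seq_len(spec$frozen)
        iact <- setdiff(seq_len(ncol(Chf)), icore)
        Cact <- Chf[, iact, drop = FALSE]
        h <- t(Cact) %*% monomer_hcore(sys, monomer) %*% Cact
        jkc <- .mo_jk(sys, Cact, Chf[, icore, drop = FALSE])
        heff <- h + 2 * jkc$J - jkc$K
        gw <- mo_eri(sys, Cact, Cact, Cact, Cact)
        H <- cpp_fci2_hamiltonian(heff, as.numeric(gw), ncol(Cact))
        sol <- cpp_davidson(H, max(1L, spec$root), 1e-10, 200L)
        gmat <- pairvec_to_g(sol$vectors[, spec$root], ncol(Cact))
        nat <- gem_natural(gmat)
        keep <- which(abs(nat$coef) > spec$trunc * max(abs(nat$coef)))
        nat$coef <- nat$coef[keep] / sqrt(sum(nat$coef[keep]^2))
        nat$U <- nat$U[, keep, drop = FALSE]
        Cs <- Cact %*% nat$U
        n <- ncol(Cs)
        # core energy for bookkeeping
        hc <- t(Chf[, icore, drop = FALSE]) %*% monomer_hcore(sys, monomer) %*%
          Chf[, icore, drop = FALSE]
        Ccore <- Chf[, icore, drop = FALSE]
        list(C = Cs, N = 2L, Dcore = 2 * Ccore %*% t(Ccore),
             struct = gem_struct(list(list(orbs = seq_len(n),
                                           g = diag(nat$coef, n, n))), n),
             energy = sol$values[spec$root], label = sprintf("FCI(fc:%d)", spec$frozen),
             C_full = Chf)
      } else stop("fci supports 2 correlated electrons (optionally above a frozen core)")
    },
    cas = {
      cs <- cas2_scf(sys, monomer, ncas = spec$ncas, core = spec$core,
                     root = spec$root, symop = symop,
                     sym_char = spec$sym_char, C0 = C0)
      isup <- c(cs$core, cs$active)
      Cs <- cs$C[, isup, drop = FALSE]
      ncoreo <- length(cs$core)
      groups <- c(lapply(seq_len(ncoreo), function(i)
        list(orbs = i, g = matrix(1, 1, 1))),
        list(list(orbs = ncoreo + seq_len(spec$ncas),
                  g = diag(cs$coef, spec$ncas, spec$ncas))))
      list(C = Cs, N = 2L * ncoreo + 2L,
           struct = gem_struct(groups, length(isup)),
           energy = cs$energy, label = sprintf("CAS(2,%d)", spec$ncas),
           character = cs$character, C_full = cs$C,
           geminal = geminal_model(list(list(orbs = ncoreo + seq_len(spec$ncas),
                                             coef = cs$coef))))
    })
  out$monomer <- monomer
  out$spec <- spec
  structure(out, class = "monomer_state")
}

#' @export
print.monomer_state <- function(x, ...) {
  cat(sprintf("monomer %s: %s, support %d orbitals, N = %d, E = %.8f\n",
              x$monomer, x$label, ncol(x$C), x$N, x$energy))
  invisible(x)
}

# dense RDMs of a monomer state over its support
monomer_dms <- function(state, kmax = 3L) {
  gs <- state$struct
  parts <- lapply(gs$groups, function(gr) {
    if (length(gr$orbs) == 1L && abs(gr$g[1, 1] - 1) < 1e-14)
      hf_rdms(gr$orbs, gs$n, kmax = kmax)
    else gem2e_rdms(gr$g, n = gs$n, orbs = gr$orbs, kmax = kmax)
  })
  Reduce(function(a, b) dms_combine(a, b, kmax = kmax), parts)
}

#' First-order SRS interaction energy from two monomer states
#'
#' Builds the interaction tensors over the monomer supports and evaluates
#' the electrostatic energy and the exchange terms through the requested
#' overlap order.
#'
#' @param sys A [build_dimer_system()] handle.
#' @param stateA,stateB [solve_monomer()] results.
#' @param order `"s2"` or `"s4"`.
#' @param path `"fast"` (factorized geminal contractions, default),
#'   `"dense"` (explicit spinorbital RDM contractions; cost grows steeply
#'   with the support size).
#' @return A `first_order_decomposition`.
#' @export
sapt_first_order <- function(sys, stateA, stateB, order = c("s4", "s2"),
                             path = c("fast", "dense")) {
  order <- match.arg(order)
  path <- match.arg(path)
  kmax <- if (order == "s4") 2L else 1L
  tn <- interaction_tensors(sys, list(C = stateA$C, N = stateA$N,
                                      Dcore = stateA$Dcore),
                            list(C = stateB$C, N = stateB$N,
                                 Dcore = stateB$Dcore))
  if (path == "fast") {
    r <- exchange_fastpath(tn, stateA$struct, stateB$struct, kmax = kmax)
    V <- r$V; P <- r$P; VP <- r$VP
  } else {
    dA <- monomer_dms(stateA, kmax = kmax + 1L)
    dB <- monomer_dms(stateB, kmax = kmax + 1L)
    S_so <- so_overlap(tn$S)
    V <- electrostatic_energy(tn, dms_spatial1(dA), dms_spatial1(dB))
    P <- VP <- numeric(kmax)
    for (k in seq_len(kmax)) {
      P[k] <- expectation_P2k(k, S_so, dA, dB)
      VP[k] <- expectation_VP2k(k, tn, dA, dB)
    }
  }
  if (kmax == 1L) assemble_first_order(V, P[1], VP[1])
  else assemble_first_order(V, P[1], VP[1], P[2], VP[2])
}
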