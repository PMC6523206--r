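# Independent oracles used across the suite.
#
# oracle_rhs() re-derives the whole-body rate equations directly from the
# model description (organ-by-organ, term-by-term, plain R), sharing only
# the parameter-vector *layout* with the compiled implementation. It is
# deliberately written with scalar loops and explicit flow bookkeeping so
# that an indexing or sign error in the compiled code cannot be replicated
# here by construction.

oracle_organs <- function() c("lung", "brain", "heart", "kidney", "liver",
                              "spleen", "stomach", "small_intestine",
                              "large_intestine", "pancreas", "gonads",
                              "bone", "muscle", "fat", "skin")

oracle_rhs <- function(y, p) {
  orgs <- oracle_organs()
  n <- length(orgs)
  sc <- function(nm) p[asunpbpk:::parm_index(nm)]
  arr <- function(nm) p[asunpbpk:::parm_index(nm, NULL)][seq_len(n)]
  gi <- function(block, i) {
    # state order: venous, arterial, then per-block organ vectors
    2 + (block - 1) * n + i
  }
  Q <- arr("q"); Lf <- arr("lf"); Vpl <- arr("v_pl"); Vis <- arr("v_is")
  Ve <- arr("v_e"); JS <- arr("j_s"); JL <- arr("j_l")
  sigS <- arr("sig_s"); sigL <- arr("sig_l")
  PSS <- arr("ps_s"); PSL <- arr("ps_l"); CLup <- arr("cl_up")
  Ttot <- arr("t_tot"); Rtot <- arr("r_tot")

  ven <- y[1]; art <- y[2]
  vt <- y[2 + 5 * n + 1]; at <- y[2 + 5 * n + 2]
  cven <- ven / sc("v_ven"); cart <- art / sc("v_art")
  dy <- numeric(length(y))

  patlak <- function(J, sig, PS, cp, ci) {
    jeff <- J * (1 - sig)
    if (PS <= 0) return(if (jeff >= 0) jeff * cp else jeff * ci)
    pe <- jeff / PS
    if (abs(pe) < 1e-6) return(PS * (cp - ci) + jeff * (cp + ci) / 2)
    if (pe > 500) return(jeff * cp)
    if (pe < -500) return(jeff * ci)
    jeff * (cp - ci * exp(-pe)) / (1 - exp(-pe))
  }

  iliver <- which(orgs == "liver")
  ikid <- which(orgs == "kidney")
  ilung <- which(orgs == "lung")
  portal <- match(c("spleen", "stomach", "small_intestine",
                    "large_intestine", "pancreas"), orgs)

  cpl <- y[gi(1, seq_len(n))] / Vpl
  cis <- y[gi(4, seq_len(n))] / Vis
  liver_in <- sum((Q[portal] - Lf[portal]) * cpl[portal])
  q_liver_in <- Q[iliver] + sum(Q[portal] - Lf[portal])

  dven <- sc("inf_rate") - Q[ilung] * cven
  dart <- (Q[ilung] - Lf[ilung]) * cpl[ilung]

  for (i in seq_len(n)) {
    apl <- y[gi(1, i)]; ae <- y[gi(2, i)]; aef <- y[gi(3, i)]
    ais <- y[gi(4, i)]; aist <- y[gi(5, i)]
    if (i == ilung) {
      inflow <- Q[i] * cven
      qout <- Q[i] - Lf[i]
    } else if (i == iliver) {
      inflow <- Q[i] * cart + liver_in
      qout <- q_liver_in - Lf[i]
      dven <- dven + qout * cpl[i]
      dart <- dart - Q[i] * cart
    } else {
      inflow <- Q[i] * cart
      qout <- Q[i] - Lf[i]
      dart <- dart - Q[i] * cart
      if (!(i %in% portal)) dven <- dven + qout * cpl[i]
    }
    flux <- patlak(JS[i], sigS[i], PSS[i], cpl[i], cis[i]) +
      patlak(JL[i], sigL[i], PSL[i], cpl[i], cis[i])
    rfree <- max(Rtot[i] - aef, 0)
    bind_r <- sc("kass") * ae * rfree / Ve[i]
    rec <- sc("krec") * aef
    dy[gi(1, i)] <- inflow - qout * cpl[i] - flux - CLup[i] * cpl[i] +
      sc("fr") * rec
    dy[gi(2, i)] <- CLup[i] * (cpl[i] + cis[i]) - sc("kdeg") * ae -
      bind_r + sc("koff_fcrn") * aef
    dy[gi(3, i)] <- bind_r - sc("koff_fcrn") * aef - rec
    bt <- 0; ut <- 0
    if (Ttot[i] > 0) {
      bt <- sc("kon_t") * ais * max(Ttot[i] - aist, 0) / Vis[i]
      ut <- sc("koff_t") * aist
      dy[gi(5, i)] <- bt - ut
    }
    dy[gi(4, i)] <- flux - Lf[i] * cis[i] - CLup[i] * cis[i] +
      (1 - sc("fr")) * rec - bt + ut
    dven <- dven + Lf[i] * cis[i]
    dy[2 + 5 * n + 3] <- dy[2 + 5 * n + 3] + sc("kdeg") * ae
    if (i == iliver && sc("k_asgr") > 0) {
      dy[gi(4, i)] <- dy[gi(4, i)] - sc("k_asgr") * ais
      dy[gi(1, i)] <- dy[gi(1, i)] - sc("k_asgr") * apl
      dy[2 + 5 * n + 4] <- dy[2 + 5 * n + 4] + sc("k_asgr") * (ais + apl)
    }
    if (i == ikid && sc("gfr_cl") > 0) {
      dy[gi(1, i)] <- dy[gi(1, i)] - sc("gfr_cl") * cpl[i]
      dy[2 + 5 * n + 5] <- dy[2 + 5 * n + 5] + sc("gfr_cl") * cpl[i]
    }
  }
  if (sc("t_ven") > 0) {
    b <- sc("kon_t") * ven * max(sc("t_ven") - vt, 0) / sc("v_ven")
    u <- sc("koff_t") * vt
    dven <- dven + u - b
    dy[2 + 5 * n + 1] <- b - u
  }
  if (sc("t_art") > 0) {
    b <- sc("kon_t") * art * max(sc("t_art") - at, 0) / sc("v_art")
    u <- sc("koff_t") * at
    dart <- dart + u - b
    dy[2 + 5 * n + 2] <- b - u
  }
  dy[1] <- dven
  dy[2] <- dart
  dy
}

# evaluate the compiled right-hand side at an arbitrary state (the static
# parameter block in the DLL is loaded by a zero-length lsoda call first)
compiled_rhs <- function(model, y, inf_rate = 0) {
  p <- model$parms
  p[asunpbpk:::parm_index("inf_rate")] <- inf_rate
  invisible(deSolve::lsoda(y = rep(0, length(model$state_names)),
                           times = c(0, 1e-8), func = "asun_derivs",
                           parms = p, dllname = "asunpbpk",
                           initfunc = "asun_initmod"))
  out <- .C("asun_derivs", as.integer(length(y)), as.double(0),
            as.double(y), ydot = double(length(y)), double(1),
            integer(1), PACKAGE = "asunpbpk")
  out$ydot
}

make_profile <- function(times, conc, lloq = 0, schedule = NULL,
                         id = "subj") {
  concentration_profile(id, times, conc, lloq = lloq,
                        dose_schedule = schedule)
}
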