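# Brute-force isotopomer-level labeling simulator, used as the independent
# oracle for the EMU machinery.  It enumerates the full 2^n isotopomer state
# of every metabolite and solves the steady-state balances by damped
# fixed-point (Jacobi) iteration; product distributions of multi-reactant
# reactions are built from the joint (outer-product) reactant distribution.
# Deliberately shares no code with the EMU simulator beyond the parsed
# network structure.

iso_input_distribution <- function(mixture, substrate, n) {
  # probability vector over 2^n isotopomers, bit i (1-based position i) heavy
  sp <- mixture$species[mixture$species$substrate == substrate, , drop = FALSE]
  out <- numeric(2^n)
  for (k in seq_len(nrow(sp))) {
    p <- ifelse(seq_len(n) %in% sp$positions[[k]], sp$purity[k],
                mixture$natural_abundance)
    # bit i (value 2^(i-1)) of the isotopomer index marks position i heavy
    out_k <- numeric(2^n)
    for (s in 0:(2^n - 1)) {
      bits <- as.integer(intToBits(s))[seq_len(n)]
      out_k[s + 1] <- prod(ifelse(bits == 1, p, 1 - p))
    }
    out <- out + sp$fraction[k] * out_k
  }
  out
}

iso_directed <- function(network) {
  # directed reactions with symmetric-reactant orientation variants
  drs <- list()
  rev_string <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (rx in network$reactions) {
    if (is.null(rx$amap)) next
    for (d in if (rx$reversible) c(1, -1) else 1) {
      if (d == 1) {
        rmet <- rx$lhs$met; ratm <- rx$amap$lhs
        pmet <- rx$rhs$met; patm <- rx$amap$rhs
      } else {
        rmet <- rx$rhs$met; ratm <- rx$amap$rhs
        pmet <- rx$lhs$met; patm <- rx$amap$lhs
      }
      sym <- which(rmet %in% network$symmetric)
      grid <- if (length(sym)) expand.grid(rep(list(c(FALSE, TRUE)), length(sym)))
      else data.frame(row.names = 1)
      for (v in seq_len(nrow(grid))) {
        atm <- ratm
        if (length(sym))
          for (j in seq_along(sym))
            if (grid[v, j]) atm[sym[j]] <- rev_string(atm[sym[j]])
        drs[[length(drs) + 1]] <- list(rxn = rx$id, dir = d, w = 1 / nrow(grid),
                                       rmet = rmet, ratm = atm,
                                       pmet = pmet, patm = patm)
      }
    }
  }
  drs
}

isotopomer_simulate <- function(network, flux, mixture, tol = 1e-13,
                                max_iter = 50000) {
  carbons <- setNames(network$mets$carbons, network$mets$met)
  balanced <- network$mets$met[network$mets$balanced & !is.na(network$mets$carbons)]
  drs <- iso_directed(network)
  fval <- function(dr) {
    ex <- if (dr$rxn %in% names(flux$exchange)) flux$exchange[[dr$rxn]] else 0
    v <- flux$net[[dr$rxn]]
    dr$w * (if (dr$dir == 1) max(v, 0) + ex else max(-v, 0) + ex)
  }
  # fixed input distributions
  state <- list()
  for (m in network$inputs)
    state[[m]] <- iso_input_distribution(mixture, m, carbons[[m]])
  for (m in balanced) {
    n <- carbons[[m]]
    nat <- iso_input_distribution(
      tracer_mixture(data.frame(substrate = m, positions = I(list(integer(0))),
                                fraction = 1, purity = 1),
                     mixture$natural_abundance), m, n)
    state[[m]] <- nat
  }
  out_flux <- setNames(numeric(length(balanced)), balanced)
  for (dr in drs) {
    v <- fval(dr)
    for (m in dr$pmet) if (m %in% balanced)
      out_flux[m] <- out_flux[m] + v
  }
  for (it in seq_len(max_iter)) {
    inflow <- lapply(setNames(balanced, balanced),
                     function(m) numeric(2^carbons[[m]]))
    for (dr in drs) {
      v <- fval(dr)
      if (v <= 0) next
      if (!all(dr$rmet %in% names(state))) next
      # joint reactant distribution over concatenated atoms
      joint <- 1
      offsets <- integer(length(dr$rmet))
      off <- 0L
      for (j in seq_along(dr$rmet)) {
        offsets[j] <- off
        dj <- state[[dr$rmet[j]]]
        nj <- carbons[[dr$rmet[j]]]
        # joint index: earlier reactants occupy lower-order bits
        joint <- as.vector(outer(joint, dj, "*"))
        off <- off + nj
      }
      ntot <- off
      # letters -> joint bit index
      letters_all <- character(0)
      for (j in seq_along(dr$rmet))
        letters_all <- c(letters_all, strsplit(dr$ratm[j], "")[[1]])
      for (occ in seq_along(dr$pmet)) {
        m <- dr$pmet[occ]
        if (!m %in% balanced) next
        pl <- strsplit(dr$patm[occ], "")[[1]]
        bitpos <- match(pl, letters_all) - 1L   # joint bit of product atom k
        np <- length(pl)
        # map every joint state to the product isotopomer index
        states <- 0:(2^ntot - 1)
        pidx <- integer(length(states))
        for (k in seq_len(np)) {
          has <- bitwAnd(states, bitwShiftL(1L, bitpos[k])) > 0
          pidx <- pidx + as.integer(has) * 2L^(k - 1L)
        }
        add <- rowsum(joint * v, pidx)
        tgt <- inflow[[m]]
        tgt[as.integer(rownames(add)) + 1L] <- tgt[as.integer(rownames(add)) + 1L] + add[, 1]
        inflow[[m]] <- tgt
      }
    }
    delta <- 0
    for (m in balanced) {
      new <- inflow[[m]] / out_flux[m]
      delta <- max(delta, max(abs(new - state[[m]])))
      state[[m]] <- new
    }
    if (delta < tol) break
  }
  if (delta >= tol) stop("isotopomer fixed point did not converge (delta ", delta, ")")
  state
}

iso_fragment_mdv <- function(state, network, fragment) {
  carbons <- setNames(network$mets$carbons, network$mets$met)
  mdv <- 1
  for (p in fragment$parts) {
    n <- carbons[[p$met]]
    d <- state[[p$met]]
    states <- 0:(2^n - 1)
    cnt <- integer(length(states))
    for (a in p$atoms)
      cnt <- cnt + as.integer(bitwAnd(states, bitwShiftL(1L, a - 1L)) > 0)
    part <- as.vector(rowsum(d, cnt))
    full <- numeric(length(p$atoms) + 1)
    full[sort(unique(cnt)) + 1] <- part
    m2 <- full
    new <- numeric(length(mdv) + length(m2) - 1)
    for (i in seq_along(mdv)) new[i:(i + length(m2) - 1)] <-
        new[i:(i + length(m2) - 1)] + mdv[i] * m2
    mdv <- new
  }
  mdv
}
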