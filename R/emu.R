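# EMU decomposition and mass-distribution-vector simulation.
#
# The decomposition traces every measured fragment back through the atom
# transition maps to the labeled substrates, collecting the minimal set of
# elementary metabolite units (EMUs).  Simulation then solves one linear
# balance system per EMU size, smallest first; condensation reactions enter
# as discrete convolutions of smaller EMUs.

emu_id <- function(met, atoms) paste0(met, "|", paste(atoms, collapse = ","))

# Expand reactions into directed variants.  Reversible reactions yield a
# forward and a backward copy; each occurrence of a rotationally symmetric
# metabolite among the *reactants* additionally doubles the copy with the
# atom string reversed, at half weight (50/50 orientation scrambling).
directed_reactions <- function(network) {
  drs <- list()
  rev_string <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (rx in network$reactions) {
    if (is.null(rx$amap)) next
    for (d in if (rx$reversible) c(1L, -1L) else 1L) {
      if (d == 1L) {
        rmet <- rx$lhs$met; ratm <- rx$amap$lhs
        pmet <- rx$rhs$met; patm <- rx$amap$rhs
      } else {
        rmet <- rx$rhs$met; ratm <- rx$amap$rhs
        pmet <- rx$lhs$met; patm <- rx$amap$lhs
      }
      sym <- which(rmet %in% network$symmetric)
      variant_sets <- if (length(sym))
        do.call(expand.grid, rep(list(c(FALSE, TRUE)), length(sym)))
      else data.frame(row.names = 1)
      for (v in seq_len(nrow(variant_sets))) {
        atm <- ratm
        if (length(sym)) {
          flip <- unlist(variant_sets[v, ])
          for (j in seq_along(sym))
            if (flip[j]) atm[sym[j]] <- rev_string(atm[sym[j]])
        }
        drs[[length(drs) + 1L]] <- list(
          rxn = rx$id, dir = d, w = 1 / nrow(variant_sets),
          rmet = rmet, ratm = atm, pmet = pmet, patm = patm)
      }
    }
  }
  drs
}

#' Decompose a network into the EMU system of a fragment panel
#'
#' Starting from the measured fragments, traces precursor dependencies
#' backwards through every (directed) reaction until only substrate-input
#' EMUs remain, and compiles per-size linear-system templates for fast
#' repeated simulation.  Symmetric metabolites contribute both orientation
#' variants at weight 0.5.
#'
#' @param network A `flux_network`.
#' @param targets List of fragment specifications (default: the network's
#'   bundled panel); each a `list(id, parts)` with parts
#'   `list(met, atoms)`.
#' @return An object of class `emu_network` with elements `emus` (table of
#'   all EMUs), `levels` (compiled per-size systems), `targets`, and the
#'   directed-reaction table.
#' @export
emu_decompose <- function(network, targets = network$fragments) {
  if (is.null(targets)) stop("no target fragments given")
  met_carbons <- stats::setNames(network$mets$carbons, network$mets$met)
  for (fr in targets)
    for (p in fr$parts) {
      if (!p$met %in% names(met_carbons)) stop("unknown metabolite ", p$met,
                                               " in fragment ", fr$id)
      nc <- met_carbons[[p$met]]
      if (!is.na(nc) && any(p$atoms < 1 | p$atoms > nc))
        stop("fragment ", fr$id, ": atoms outside 1..", nc, " of ", p$met)
    }
  drs <- directed_reactions(network)
  # index directed reactions by product metabolite
  prod_index <- new.env(parent = emptyenv())
  for (k in seq_along(drs))
    for (m in unique(drs[[k]]$pmet))
      assign(m, c(mget(m, prod_index, ifnotfound = list(NULL))[[1]], k), prod_index)

  emus <- list()      # id -> list(met, atoms, size, input)
  trans <- list()     # id -> list of list(rxn, dir, w0, sources = char ids)
  queue <- character(0)
  add_emu <- function(met, atoms) {
    id <- emu_id(met, atoms)
    if (is.null(emus[[id]])) {
      emus[[id]] <<- list(met = met, atoms = atoms, size = length(atoms),
                          input = met %in% network$inputs)
      if (!emus[[id]]$input) queue <<- c(queue, id)
    }
    id
  }
  for (fr in targets)
    for (p in fr$parts) add_emu(p$met, sort(p$atoms))

  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    e <- emus[[id]]
    tlist <- list()
    for (k in mget(e$met, prod_index, ifnotfound = list(NULL))[[1]]) {
      dr <- drs[[k]]
      for (occ in which(dr$pmet == e$met)) {
        letters <- strsplit(dr$patm[occ], "")[[1]][e$atoms]
        parts <- list()
        taken <- 0L
        for (j in seq_along(dr$rmet)) {
          pos <- which(strsplit(dr$ratm[j], "")[[1]] %in% letters)
          if (length(pos)) {
            parts[[length(parts) + 1L]] <- list(met = dr$rmet[j], atoms = pos)
            taken <- taken + length(pos)
          }
        }
        if (taken != length(letters))
          stop("reaction ", dr$rxn, " does not conserve carbons of EMU ", id)
        src <- vapply(parts, function(p) add_emu(p$met, sort(p$atoms)), "")
        tlist[[length(tlist) + 1L]] <- list(rxn = dr$rxn, dir = dr$dir,
                                            w0 = dr$w, sources = src)
      }
    }
    if (length(tlist) == 0)
      stop("EMU ", id, " has no producing reaction (disconnected from substrates)")
    trans[[id]] <- tlist
  }

  ids <- names(emus)
  # deterministic ordering: by size, then metabolite name, then atom set
  ord <- order(vapply(emus, `[[`, 0L, "size"), ids)
  ids <- ids[ord]
  emus <- emus[ids]
  idx <- stats::setNames(seq_along(ids), ids)
  size <- vapply(emus, `[[`, 0L, "size")
  input <- vapply(emus, `[[`, TRUE, "input")

  dr_rxn <- vapply(drs, `[[`, "", "rxn")
  dr_dir <- vapply(drs, `[[`, 0L, "dir")
  dr_key <- paste0(dr_rxn, "/", dr_dir)
  key_of <- function(rxn, dir) match(paste0(rxn, "/", dir), unique(dr_key))
  ukeys <- unique(dr_key)
  urxn <- dr_rxn[!duplicated(dr_key)]
  udir <- dr_dir[!duplicated(dr_key)]

  levels <- list()
  for (k in sort(unique(size[!input]))) {
    un <- ids[size == k & !input]
    loc <- stats::setNames(seq_along(un), un)
    t_target <- integer(0); t_dr <- integer(0); t_w0 <- numeric(0)
    t_col <- integer(0)            # >0: same-level unknown single source
    t_src <- list()                # integer global indices for rhs terms
    for (id in un) {
      for (tr in trans[[id]]) {
        di <- key_of(tr$rxn, tr$dir)
        t_target <- c(t_target, loc[[id]])
        t_dr <- c(t_dr, di)
        t_w0 <- c(t_w0, tr$w0)
        s <- tr$sources
        if (length(s) == 1 && !input[idx[s]] && size[idx[s]] == k) {
          t_col <- c(t_col, loc[[s]])
          t_src <- c(t_src, list(integer(0)))
        } else {
          t_col <- c(t_col, 0L)
          t_src <- c(t_src, list(unname(idx[s])))
        }
      }
    }
    levels[[as.character(k)]] <- list(
      size = k, un = unname(idx[un]), loc_ids = un,
      t_target = t_target, t_dr = t_dr, t_w0 = t_w0, t_col = t_col,
      t_src = t_src)
  }

  structure(list(
    ids = ids, met = vapply(emus, `[[`, "", "met"),
    atoms = lapply(emus, `[[`, "atoms"), size = size, input = input,
    levels = levels, dr_rxn = urxn, dr_dir = udir,
    targets = targets, n_emus = length(ids)), class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat("<emu_network>", x$n_emus, "EMUs (", sum(x$input), "substrate inputs ) in",
      length(x$levels), "size levels\n")
  cat("  targets:", paste(vapply(x$targets, `[[`, "", "id"), collapse = ", "), "\n")
  invisible(x)
}

#' Substrate-input EMU mass distributions
#'
#' @param emu_net An `emu_network`.
#' @param mixture A `tracer_mixture`.
#' @return List (by EMU id) of MDVs for the input EMUs.
#' @export
emu_input_mdvs <- function(emu_net, mixture) {
  out <- list()
  for (i in which(emu_net$input))
    out[[emu_net$ids[i]]] <-
      substrate_emu_mdv(mixture, emu_net$met[i], emu_net$atoms[[i]])
  out
}

directed_flux_values <- function(emu_net, flux) {
  net <- flux$net[emu_net$dr_rxn]
  ex <- rep(0, length(net))
  has <- emu_net$dr_rxn %in% names(flux$exchange)
  ex[has] <- flux$exchange[emu_net$dr_rxn[has]]
  ifelse(emu_net$dr_dir == 1L, pmax(net, 0) + ex, pmax(-net, 0) + ex)
}

#' Simulate measured fragment MDVs from a flux map and tracer mixture
#'
#' Solves, for each EMU size level in increasing order, the linear balance
#' system `(A(v) - D(v)) X = -B(v) Y` in which unknown EMU MDVs at that size
#' are coupled through flux-weighted transitions, with inputs given by
#' substrate EMUs and convolutions of smaller EMUs.  Fragment MDVs are the
#' convolutions of their part EMUs.
#'
#' @param emu_net An `emu_network` from [emu_decompose()].
#' @param flux A `flux_map` (any normalization; simulated MDVs are invariant
#'   to uniform flux scaling).
#' @param mixture A `tracer_mixture`, or `NULL` if `inputs` is given.
#' @param inputs Optional precomputed [emu_input_mdvs()] list (saves time in
#'   repeated fitting calls).
#' @return Named list of fragment MDVs, with attribute `"emus"` holding the
#'   MDVs of every EMU in the system.
#' @export
simulate_mdvs <- function(emu_net, flux, mixture = NULL, inputs = NULL) {
  if (is.null(inputs)) {
    if (is.null(mixture)) stop("either mixture or inputs must be supplied")
    inputs <- emu_input_mdvs(emu_net, mixture)
  }
  f <- directed_flux_values(emu_net, flux)
  mdvs <- vector("list", emu_net$n_emus)
  for (id in names(inputs)) mdvs[[match(id, emu_net$ids)]] <- inputs[[id]]

  for (lvl in emu_net$levels) {
    nu <- length(lvl$un)
    w <- lvl$t_w0 * f[lvl$t_dr]
    keep <- w > 1e-14
    out_flux <- numeric(nu)
    tt <- lvl$t_target[keep]
    agg <- rowsum(w[keep], tt)
    out_flux[as.integer(rownames(agg))] <- agg[, 1]
    if (any(out_flux <= 1e-12)) {
      dead <- lvl$loc_ids[out_flux <= 1e-12]
      stop("singular EMU system at size ", lvl$size,
           ": no flux into EMU ", paste(dead, collapse = ", "))
    }
    M <- matrix(0, nu, nu)
    b <- matrix(0, nu, lvl$size + 1)
    for (r in which(keep)) {
      i <- lvl$t_target[r]
      if (lvl$t_col[r] > 0L) {
        M[i, lvl$t_col[r]] <- M[i, lvl$t_col[r]] + w[r]
      } else {
        src <- lvl$t_src[[r]]
        m <- mdvs[[src[1]]]
        if (length(src) > 1)
          for (s in src[-1]) m <- mdv_convolve(m, mdvs[[s]])
        b[i, ] <- b[i, ] + w[r] * m
      }
    }
    diag(M) <- diag(M) - out_flux
    X <- tryCatch(solve(M, -b), error = function(e)
      stop("singular EMU system at size ", lvl$size, " (disconnected EMU among: ",
           paste(lvl$loc_ids, collapse = ", "), ")"))
    for (j in seq_len(nu)) mdvs[[lvl$un[j]]] <- X[j, ]
  }

  res <- list()
  for (fr in emu_net$targets) {
    m <- NULL
    for (p in fr$parts) {
      pm <- mdvs[[match(emu_id(p$met, sort(p$atoms)), emu_net$ids)]]
      m <- if (is.null(m)) pm else mdv_convolve(m, pm)
    }
    res[[fr$id]] <- m
  }
  names(mdvs) <- emu_net$ids
  attr(res, "emus") <- mdvs
  res
}

#' Natural-abundance correction of a measured MDV
#'
#' Applies (`mode = "uncorrect"`) or removes (`mode = "correct"`) the
#' binomial natural-abundance broadening of the backbone carbons: entry
#' `(i, j)` of the correction matrix is the probability that a molecule
#' with `j` tracer-labeled carbons appears at mass `M+i` given that each of
#' the remaining `n - j` carbons is heavy with probability `abundance`.
#' Only carbon-backbone atoms are modeled (no derivatization Si/H/N/O
#' correction).
#'
#' @param raw A valid MDV.
#' @param n_backbone Number of backbone carbons (`length(raw) - 1`).
#' @param mode `"correct"` (solve against the matrix) or `"uncorrect"`
#'   (multiply by it).
#' @param abundance Natural 13C abundance.
#' @return Corrected or uncorrected MDV (renormalized to sum 1).
#' @export
apply_natural_abundance_correction <- function(raw, n_backbone,
                                               mode = c("correct", "uncorrect"),
                                               abundance = NATURAL_13C) {
  mode <- match.arg(mode)
  n <- n_backbone
  if (length(raw) != n + 1) stop("raw MDV must have length n_backbone + 1")
  C <- matrix(0, n + 1, n + 1)
  for (j in 0:n)
    for (i in j:n)
      C[i + 1, j + 1] <- stats::dbinom(i - j, n - j, abundance)
  if (mode == "uncorrect") return(drop(C %*% raw))
  x <- drop(solve(C, raw))
  if (any(x < -1e-6))
    stop("natural-abundance correction produced negative fractions (< -1e-6); ",
         "input MDV inconsistent with the backbone size")
  x[x < 0] <- 0
  x / sum(x)
}

#' Whole-system 13C balance of a simulated labeling state
#'
#' At isotopic steady state the molar flow of 13C entering through the
#' substrates equals the flow leaving through secreted products, biomass
#' drains and CO2.  Computes both sides from a flux map and the simulated
#' pool MDVs.
#'
#' @param network A `flux_network`.
#' @param flux A `flux_map`.
#' @param mixture A `tracer_mixture`.
#' @return List with `inflow`, `outflow` (mol 13C per 100 units of uptake,
#'   on the map's flux scale) and `relative_gap`.
#' @export
carbon_labeling_balance <- function(network, flux, mixture) {
  moles_13C <- function(mdv) sum((seq_along(mdv) - 1) * mdv)
  # boundary pools: balanced reactants of reactions producing unbalanced,
  # non-input metabolites
  bal <- network$mets$met[network$mets$balanced]
  out_terms <- list()
  for (rx in network$reactions) {
    sink_products <- setdiff(rx$rhs$met, c(bal, network$inputs))
    if (!length(sink_products)) next
    for (k in seq_len(nrow(rx$lhs)))
      if (rx$lhs$met[k] %in% bal)
        out_terms[[length(out_terms) + 1L]] <-
          list(rxn = rx$id, met = rx$lhs$met[k], coef = rx$lhs$coef[k])
  }
  pools <- unique(vapply(out_terms, `[[`, "", "met"))
  carbons <- stats::setNames(network$mets$carbons, network$mets$met)
  targets <- lapply(pools, function(m)
    list(id = m, parts = list(list(met = m, atoms = seq_len(carbons[[m]])))))
  emu_net <- emu_decompose(network, targets)
  sim <- simulate_mdvs(emu_net, flux, mixture)
  outflow <- 0
  for (tm in out_terms)
    outflow <- outflow + flux$net[[tm$rxn]] * tm$coef * moles_13C(sim[[tm$met]])
  inflow <- 0
  for (uid in network$uptakes) {
    rx <- network$reactions[[uid]]
    for (k in seq_len(nrow(rx$lhs)))
      if (rx$lhs$met[k] %in% network$inputs) {
        nC <- carbons[[rx$lhs$met[k]]]
        m <- substrate_emu_mdv(mixture, rx$lhs$met[k], seq_len(nC))
        inflow <- inflow + flux$net[[uid]] * rx$lhs$coef[k] * moles_13C(m)
      }
  }
  list(inflow = unname(inflow), outflow = unname(outflow),
       relative_gap = unname(abs(inflow - outflow) / max(inflow, 1e-12)))
}
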