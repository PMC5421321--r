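COMPARTMENTS <- c(c = "cytosol", m = "mitochondrion", e = "extracellular")

split_met <- function(x) {
  comp <- sub("^.*\\.", "", x)
  if (!all(comp %in% names(COMPARTMENTS)))
    stop("unknown compartment tag in metabolite(s): ",
         paste(x[!comp %in% names(COMPARTMENTS)], collapse = ", "))
  data.frame(name = sub("\\.[cme]$", "", x), compartment = unname(COMPARTMENTS[comp]),
             stringsAsFactors = FALSE)
}

parse_terms <- function(side) {
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  coef <- rep(1, length(terms))
  met <- terms
  has_coef <- grepl("^[0-9.]+\\s+", terms)
  coef[has_coef] <- as.numeric(sub("\\s.*$", "", terms[has_coef]))
  met[has_coef] <- sub("^[0-9.]+\\s+", "", terms[has_coef])
  data.frame(met = met, coef = coef, stringsAsFactors = FALSE)
}

parse_reaction_line <- function(line) {
  parts <- trimws(strsplit(line, "|", fixed = TRUE)[[1]])
  if (length(parts) != 3)
    stop("malformed reaction line (need 'id: eq | atoms | rev'): ", line)
  id <- trimws(sub(":.*$", "", parts[1]))
  eq <- trimws(sub("^[^:]*:", "", parts[1]))
  sides <- trimws(strsplit(eq, "->", fixed = TRUE)[[1]])
  if (length(sides) != 2) stop("reaction ", id, ": missing '->'")
  lhs <- parse_terms(sides[1])
  rhs <- parse_terms(sides[2])
  amap <- NULL
  if (parts[2] != "-") {
    asides <- trimws(strsplit(parts[2], "->", fixed = TRUE)[[1]])
    if (length(asides) != 2) stop("reaction ", id, ": malformed atom map")
    al <- trimws(strsplit(asides[1], "+", fixed = TRUE)[[1]])
    ar <- trimws(strsplit(asides[2], "+", fixed = TRUE)[[1]])
    if (length(al) != nrow(lhs) || length(ar) != nrow(rhs))
      stop("reaction ", id, ": atom map terms do not align with stoichiometry")
    amap <- list(lhs = al, rhs = ar)
  }
  rev <- match.arg(parts[3], c("rev", "irr"))
  list(id = id, lhs = lhs, rhs = rhs, amap = amap, reversible = rev == "rev")
}

format_terms <- function(df) {
  paste(ifelse(df$coef == 1, df$met, paste(format(df$coef, trim = TRUE,
        scientific = FALSE), df$met)), collapse = " + ")
}

format_reaction_line <- function(rx) {
  amap <- if (is.null(rx$amap)) "-" else
    paste(paste(rx$amap$lhs, collapse = " + "), "->",
          paste(rx$amap$rhs, collapse = " + "))
  sprintf("%s: %s -> %s | %s | %s", rx$id,
          format_terms(rx$lhs), format_terms(rx$rhs), amap,
          if (rx$reversible) "rev" else "irr")
}

#' Read a metabolic-network configuration file
#'
#' Parses the plain-text network format used by the bundled *Yarrowia
#' lipolytica* models: one reaction per line
#' (`"id: A + B -> C + D | abc + d -> abcd | rev"`), with directive lines
#' `input:` (extracellular substrates), `symmetric:` (rotationally symmetric
#' metabolites such as succinate and fumarate, scrambled 50/50 on
#' consumption) and `unbalanced:` (intracellular sink pools exempt from the
#' steady-state balance).  Compartments are metabolite suffixes
#' (`.c`/`.m`/`.e`); carbon counts are inferred from the atom-transition
#' strings.
#'
#' @param path Path to a configuration file, or a character vector of lines
#'   via `text`.
#' @param text Optional character vector of configuration lines (used in
#'   place of `path`).
#' @return An object of class `flux_network`: a list with elements
#'   `reactions` (named list), `mets` (data frame with `met`, `name`,
#'   `compartment`, `carbons`, `balanced`), `inputs`, `symmetric`,
#'   `uptakes` (ids of substrate-uptake reactions), and `fragments`
#'   (measured-fragment panel, filled by [build_yarrowia_network()]).
#' @seealso [write_network_config()], [build_yarrowia_network()]
#' @export
read_network_config <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  directive <- function(key) {
    hits <- grep(paste0("^", key, ":"), lines, value = TRUE)
    unlist(lapply(hits, function(h) strsplit(trimws(sub("^[a-z]+:", "", h)),
                                             "\\s+")[[1]]))
  }
  inputs <- directive("input")
  symmetric <- directive("symmetric")
  unbalanced <- directive("unbalanced")
  rlines <- lines[!grepl("^(input|symmetric|unbalanced):", lines)]
  reactions <- lapply(rlines, parse_reaction_line)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(names(reactions)))
    stop("duplicate reaction ids: ",
         paste(unique(names(reactions)[duplicated(names(reactions))]),
               collapse = ", "))

  all_mets <- unique(unlist(lapply(reactions, function(rx) c(rx$lhs$met, rx$rhs$met))))
  carbons <- rep(NA_integer_, length(all_mets))
  names(carbons) <- all_mets
  for (rx in reactions) {
    if (is.null(rx$amap)) next
    for (side in c("lhs", "rhs")) {
      mets <- rx[[side]]$met
      strs <- rx$amap[[side]]
      for (k in seq_along(mets)) {
        n <- nchar(strs[k])
        if (is.na(carbons[mets[k]])) carbons[mets[k]] <- n
        else if (carbons[mets[k]] != n)
          stop("inconsistent carbon count for ", mets[k], " in reaction ", rx$id)
      }
    }
  }
  mets <- cbind(data.frame(met = all_mets, stringsAsFactors = FALSE),
                split_met(all_mets))
  mets$carbons <- unname(carbons[mets$met])
  mets$balanced <- mets$compartment != "extracellular" &
    !(mets$met %in% unbalanced) & !(mets$met %in% inputs)
  uptakes <- names(reactions)[vapply(reactions, function(rx)
    any(rx$lhs$met %in% inputs), TRUE)]
  net <- structure(list(reactions = reactions, mets = mets, inputs = inputs,
                        symmetric = symmetric, unbalanced = unbalanced,
                        uptakes = uptakes, fragments = NULL, mode = NULL),
                   class = "flux_network")
  issues <- check_network(net)
  if (length(issues)) stop("invalid network:\n  ", paste(issues, collapse = "\n  "))
  net
}

#' Write a metabolic-network configuration file
#'
#' Serializes a `flux_network` back to the plain-text format read by
#' [read_network_config()]; reading the written file reproduces the network
#' (round trip).
#'
#' @param network A `flux_network`.
#' @param path Output file path.  If `NULL`, the lines are returned invisibly
#'   without writing.
#' @return Invisibly, the character vector of configuration lines.
#' @export
write_network_config <- function(network, path = NULL) {
  lines <- c(paste("input:", paste(network$inputs, collapse = " ")),
             if (length(network$symmetric))
               paste("symmetric:", paste(network$symmetric, collapse = " ")),
             if (length(network$unbalanced))
               paste("unbalanced:", paste(network$unbalanced, collapse = " ")),
             vapply(network$reactions, format_reaction_line, ""))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

check_network <- function(network) {
  issues <- character(0)
  S <- stoich_matrix(network)
  rev_flag <- vapply(network$reactions, `[[`, TRUE, "reversible")[colnames(S)]
  bal <- network$mets$met[network$mets$balanced]
  for (m in bal) {
    row <- S[m, ]
    if (!any(row > 0 | (row != 0 & rev_flag)))
      issues <- c(issues, paste0("balanced metabolite ", m,
                                 " has no producing reaction"))
    if (!any(row < 0 | (row != 0 & rev_flag)))
      issues <- c(issues, paste0("balanced metabolite ", m,
                                 " has no consuming reaction"))
  }
  if (length(network$uptakes) == 0)
    issues <- c(issues, "no substrate uptake reaction found")
  issues
}

#' Stoichiometric matrix of a network
#'
#' @param network A `flux_network`.
#' @param balanced_only If `TRUE` (default) restrict rows to balanced
#'   (steady-state) metabolites.
#' @return A numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(network, balanced_only = FALSE) {
  mets <- network$mets$met
  S <- matrix(0, length(mets), length(network$reactions),
              dimnames = list(mets, names(network$reactions)))
  for (rx in network$reactions) {
    for (k in seq_len(nrow(rx$lhs)))
      S[rx$lhs$met[k], rx$id] <- S[rx$lhs$met[k], rx$id] - rx$lhs$coef[k]
    for (k in seq_len(nrow(rx$rhs)))
      S[rx$rhs$met[k], rx$id] <- S[rx$rhs$met[k], rx$id] + rx$rhs$coef[k]
  }
  if (balanced_only) S[network$mets$met[network$mets$balanced], , drop = FALSE]
  else S
}

#' Validate per-reaction carbon-atom conservation
#'
#' Checks, for every reaction that carries an atom-transition map, that the
#' reactant carbon labels form a duplicate-free set and that the product
#' labels are exactly a permutation of them (every carbon is conserved; CO2
#' is an explicit tracked product, so no mapped reaction may lose carbon).
#' Reactions without atom maps (biomass and lumped drains) are skipped.
#'
#' @param network A `flux_network`.
#' @return A character vector of human-readable violation reports; empty if
#'   the network validates.
#' @export
validate_carbon_balance <- function(network) {
  violations <- character(0)
  for (rx in network$reactions) {
    if (is.null(rx$amap)) next
    lhs_letters <- unlist(strsplit(paste(rx$amap$lhs, collapse = ""), ""))
    rhs_letters <- unlist(strsplit(paste(rx$amap$rhs, collapse = ""), ""))
    if (anyDuplicated(lhs_letters))
      violations <- c(violations, paste0(rx$id, ": duplicated reactant carbon label(s) ",
        paste(unique(lhs_letters[duplicated(lhs_letters)]), collapse = ",")))
    if (anyDuplicated(rhs_letters))
      violations <- c(violations, paste0(rx$id, ": duplicated product carbon label(s) ",
        paste(unique(rhs_letters[duplicated(rhs_letters)]), collapse = ",")))
    miss <- setdiff(rhs_letters, lhs_letters)
    if (length(miss))
      violations <- c(violations, paste0(rx$id, ": product label(s) ",
        paste(miss, collapse = ","), " not found among reactants"))
    lost <- setdiff(lhs_letters, rhs_letters)
    if (length(lost))
      violations <- c(violations, paste0(rx$id, ": reactant label(s) ",
        paste(lost, collapse = ","), " not carried to any product"))
  }
  violations
}

#' @export
print.flux_network <- function(x, ...) {
  cat("<flux_network>", if (!is.null(x$mode)) paste0("(", x$mode, " mode)"), "\n")
  cat("  reactions:  ", length(x$reactions),
      " (", sum(vapply(x$reactions, `[[`, TRUE, "reversible")), " reversible)\n", sep = "")
  cat("  metabolites: ", nrow(x$mets), " (", sum(x$mets$balanced), " balanced)\n", sep = "")
  cat("  substrates: ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  if (!is.null(x$fragments))
    cat("  fragments:  ", paste(vapply(x$fragments, `[[`, "", "id"), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# ---- flux maps ---------------------------------------------------------------

#' Construct a flux map
#'
#' A flux map assigns a net flux to every reaction and a nonnegative
#' exchange (bidirectional) flux to every reversible reaction.  The
#' `basis` records the normalization: `"absolute"` or the id(s) of the
#' substrate-uptake reaction(s) whose summed flux was scaled to 100.
#'
#' @param net Named numeric vector of net fluxes (one entry per reaction).
#' @param exchange Named numeric vector of exchange fluxes for reversible
#'   reactions; missing reactions default to 0.
#' @param basis `"absolute"` or a character vector of basis reaction ids.
#' @param network Optional `flux_network` used to validate names and
#'   irreversibility signs.
#' @return An object of class `flux_map`.
#' @export
flux_map <- function(net, exchange = NULL, basis = "absolute", network = NULL) {
  if (is.null(names(net))) stop("net fluxes must be named by reaction id")
  if (!is.null(network)) {
    missing <- setdiff(names(network$reactions), names(net))
    if (length(missing))
      stop("flux map is missing reaction(s): ", paste(missing, collapse = ", "))
    net <- net[names(network$reactions)]
    rev_ids <- names(network$reactions)[vapply(network$reactions, `[[`, TRUE, "reversible")]
    ex <- stats::setNames(rep(0, length(rev_ids)), rev_ids)
    if (!is.null(exchange)) ex[names(exchange)] <- exchange
    exchange <- ex
  } else if (is.null(exchange)) exchange <- stats::setNames(numeric(0), character(0))
  if (any(exchange < 0)) stop("exchange fluxes must be nonnegative")
  structure(list(net = net, exchange = exchange, basis = basis),
            class = "flux_map")
}

#' @export
print.flux_map <- function(x, ...) {
  cat("<flux_map> basis:",
      if (identical(x$basis, "absolute")) "absolute"
      else paste0(paste(x$basis, collapse = "+"), " = 100"), "\n")
  print(round(x$net, 3))
  invisible(x)
}

#' Steady-state residual of a flux map
#'
#' Computes `S %*% v` over the balanced metabolites.  At metabolic steady
#' state every entry is zero.
#'
#' @param network A `flux_network`.
#' @param flux A `flux_map` covering all reactions.
#' @return Named numeric vector of residuals (one per balanced metabolite),
#'   with attribute `max_abs`.
#' @export
steady_state_residual <- function(network, flux) {
  missing <- setdiff(names(network$reactions), names(flux$net))
  if (length(missing))
    stop("flux map is missing reaction(s): ", paste(missing, collapse = ", "))
  S <- stoich_matrix(network, balanced_only = TRUE)
  r <- drop(S %*% flux$net[colnames(S)])
  attr(r, "max_abs") <- max(abs(r))
  r
}

#' Normalize a flux map to a substrate-uptake basis
#'
#' Rescales all net and exchange fluxes so that the summed flux through the
#' basis reaction(s) equals 100, the convention used for reporting relative
#' flux distributions ("% of C-source uptake").  For dual-substrate maps,
#' pass both uptake reaction ids; their sum acts as a pseudo-reaction.
#'
#' @param flux A `flux_map`.
#' @param basis_reaction Character vector of one or more reaction ids.
#' @return A normalized `flux_map` (basis recorded); steady state and flux
#'   ratios are preserved.
#' @export
normalize_fluxes <- function(flux, basis_reaction) {
  if (!all(basis_reaction %in% names(flux$net)))
    stop("unknown basis reaction(s): ",
         paste(setdiff(basis_reaction, names(flux$net)), collapse = ", "))
  v <- sum(flux$net[basis_reaction])
  if (!is.finite(v) || v <= 0)
    stop("basis flux must be positive; got ", v)
  f <- 100 / v
  flux_map(flux$net * f, flux$exchange * f, basis = basis_reaction)
}

# ---- free-flux parameterization ---------------------------------------------

#' Affine free-flux parameterization of the steady-state flux space
#'
#' Selects a minimal set of free net fluxes such that, together with the
#' steady-state balances `S v = 0` and the normalization constraint
#' (summed substrate uptake = `basis_value`), every net flux is an affine
#' function `v = d + C v_free` of the free fluxes.  Free reactions are
#' chosen greedily from `prefer` first, so that interpretable fluxes (PPP
#' entry, pyruvate carboxylase, citrate secretion, glycerol uptake share)
#' act as the coordinates.
#'
#' @param network A `flux_network`.
#' @param prefer Character vector of preferred free reaction ids.
#' @param basis_value Total substrate uptake the completion is pinned to
#'   (default 100).
#' @return A list with `free` (ids), `d`, `C`, `ids` (reaction order),
#'   `irreversible` (ids with a nonnegativity constraint), `reversible`,
#'   and `nfree`.
#' @export
flux_parameterization <- function(network,
                                  prefer = c("g6pdh", "pc", "citsec", "glol_upt",
                                             "idh", "lip"),
                                  basis_value = 100) {
  S <- stoich_matrix(network, balanced_only = TRUE)
  ids <- colnames(S)
  n <- length(ids)
  upt <- as.numeric(ids %in% network$uptakes)
  A <- rbind(S, uptake = upt)
  b <- c(rep(0, nrow(S)), basis_value)
  rank0 <- qr(A)$rank
  nfree <- n - rank0
  free <- character(0)
  cur <- A
  for (cand in c(intersect(prefer, ids), setdiff(ids, c(prefer, network$uptakes)))) {
    if (length(free) == nfree) break
    e <- as.numeric(ids == cand)
    trial <- rbind(cur, e)
    if (qr(trial)$rank > qr(cur)$rank) {
      free <- c(free, cand)
      cur <- trial
    }
  }
  if (length(free) != nfree)
    stop("could not select ", nfree, " independent free fluxes")
  QR <- qr(cur)
  d <- qr.coef(QR, c(b, rep(0, nfree)))
  C <- matrix(0, n, nfree, dimnames = list(ids, free))
  for (k in seq_len(nfree)) {
    rhs <- c(rep(0, length(b)), as.numeric(seq_len(nfree) == k))
    C[, k] <- qr.coef(QR, rhs)
  }
  rev_flag <- vapply(network$reactions, `[[`, TRUE, "reversible")[ids]
  structure(list(free = free, d = d, C = C, ids = ids,
                 irreversible = ids[!rev_flag], reversible = ids[rev_flag],
                 nfree = nfree, basis_value = basis_value,
                 uptakes = network$uptakes),
            class = "flux_parameterization")
}

#' Complete a flux map from free net fluxes
#'
#' @param param A [flux_parameterization()].
#' @param vfree Named (or positionally ordered) numeric vector of free net
#'   fluxes.
#' @param exchange Optional named exchange fluxes for reversible reactions.
#' @return A `flux_map` normalized to the parameterization's uptake basis.
#' @export
complete_flux <- function(param, vfree, exchange = NULL) {
  if (!is.null(names(vfree))) vfree <- vfree[param$free]
  if (length(vfree) != param$nfree) stop("expected ", param$nfree, " free fluxes")
  net <- drop(param$d + param$C %*% vfree)
  names(net) <- param$ids
  ex <- stats::setNames(rep(0, length(param$reversible)), param$reversible)
  if (!is.null(exchange)) ex[names(exchange)] <- exchange
  flux_map(net, ex, basis = param$uptakes)
}

#' Dimension of the steady-state null space
#'
#' @param network A `flux_network`.
#' @return Integer: number of degrees of freedom of `S v = 0` (before any
#'   uptake normalization constraint).
#' @export
null_space_dim <- function(network) {
  S <- stoich_matrix(network, balanced_only = TRUE)
  ncol(S) - qr(S)$rank
}
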