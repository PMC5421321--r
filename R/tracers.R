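# Tracer mixtures and substrate EMU mass distributions.

#' Default natural 13C abundance (atom fraction)
#' @export
NATURAL_13C <- 0.0107

#' Construct a tracer mixture
#'
#' A tracer mixture lists, per substrate pool, the isotopic species present:
#' which carbon positions are 13C-enriched, the mole fraction of the species
#' within its substrate pool, and the isotopic purity of the enriched
#' positions.  Unenriched positions carry the natural 13C abundance.
#' Positional labeling is assumed independent within a species, the standard
#' assumption for commercial tracers.
#'
#' @param species A data frame with columns `substrate` (metabolite id, e.g.
#'   `"GLC.e"`), `positions` (list column of integer vectors; `integer(0)`
#'   for naturally labeled material), `fraction`, and `purity`.
#' @param natural_abundance Natural 13C atom fraction (default 0.0107).
#' @return An object of class `tracer_mixture`.
#' @export
tracer_mixture <- function(species, natural_abundance = NATURAL_13C) {
  stopifnot(is.data.frame(species),
            all(c("substrate", "positions", "fraction", "purity") %in% names(species)))
  if (any(species$fraction < 0 | species$fraction > 1))
    stop("species fractions must lie in [0, 1]")
  for (s in unique(species$substrate)) {
    tot <- sum(species$fraction[species$substrate == s])
    if (abs(tot - 1) > 1e-12)
      stop("fractions for substrate ", s, " sum to ", tot, ", not 1")
  }
  structure(list(species = species, natural_abundance = natural_abundance),
            class = "tracer_mixture")
}

#' @export
print.tracer_mixture <- function(x, ...) {
  cat("<tracer_mixture> natural abundance", x$natural_abundance, "\n")
  for (k in seq_len(nrow(x$species))) {
    sp <- x$species[k, ]
    pos <- sp$positions[[1]]
    cat(sprintf("  %-8s %4.0f%%  %s (purity %.2f)\n", sp$substrate,
                100 * sp$fraction,
                if (length(pos)) paste0("13C at C", paste(pos, collapse = ",C"))
                else "naturally labeled", sp$purity))
  }
  invisible(x)
}

new_species <- function(substrate, positions, fraction, purity = 0.99) {
  data.frame(substrate = substrate, positions = I(list(as.integer(positions))),
             fraction = fraction, purity = purity)
}

#' Bundled tracer recipes
#'
#' The four labeling recipes used for the *Y. lipolytica* cultivations:
#' \describe{
#'   \item{`glc_1C`}{100\% 1-13C glucose, 99 atom-\% purity.}
#'   \item{`glc_U20`}{20\% U-13C6 glucose + 80\% naturally labeled glucose.}
#'   \item{`glol_U20`}{20\% U-13C3 glycerol + 80\% naturally labeled glycerol.}
#'   \item{`dual_mix`}{Glycerol pool: 50\% U-13C3 + 50\% natural; glucose
#'     pool: 40\% 1-13C + 60\% natural (the stated 50/20/30 w/w recipe of the
#'     total C-source, partitioned per substrate pool).}
#' }
#'
#' @param name Recipe name.
#' @param natural_abundance Natural 13C atom fraction.
#' @return A `tracer_mixture`.
#' @export
bundled_mixture <- function(name = c("glc_1C", "glc_U20", "glol_U20", "dual_mix"),
                            natural_abundance = NATURAL_13C) {
  name <- match.arg(name)
  sp <- switch(name,
    glc_1C = new_species("GLC.e", 1, 1.0),
    glc_U20 = rbind(new_species("GLC.e", 1:6, 0.2),
                    new_species("GLC.e", integer(0), 0.8)),
    glol_U20 = rbind(new_species("GLOL.e", 1:3, 0.2),
                     new_species("GLOL.e", integer(0), 0.8)),
    dual_mix = rbind(new_species("GLOL.e", 1:3, 0.5),
                     new_species("GLOL.e", integer(0), 0.5),
                     new_species("GLC.e", 1, 0.2 / 0.5),
                     new_species("GLC.e", integer(0), 0.3 / 0.5)))
  tracer_mixture(sp, natural_abundance)
}

#' Convolve two mass distribution vectors
#'
#' The MDV of the union of two independent carbon sets is the discrete
#' convolution of their MDVs.
#'
#' @param a,b Numeric MDVs (`M+0 ... M+n`).
#' @return Numeric MDV of length `length(a) + length(b) - 1`.
#' @export
mdv_convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  out
}

mdv_from_probs <- function(p) {
  out <- 1
  for (pi in p) out <- mdv_convolve(out, c(1 - pi, pi))
  out
}

#' Mass distribution of a substrate EMU under a tracer mixture
#'
#' Computes the MDV of the elementary metabolite unit formed by `atoms` of
#' `substrate`: per species, each enriched position is heavy with
#' probability equal to the isotopic purity and each other position with the
#' natural abundance; the mixture MDV is the fraction-weighted sum over
#' species.
#'
#' @param mixture A `tracer_mixture`.
#' @param substrate Substrate metabolite id (e.g. `"GLC.e"`).
#' @param atoms Integer vector of 1-based carbon positions.
#' @return Numeric MDV of length `length(atoms) + 1`.
#' @export
substrate_emu_mdv <- function(mixture, substrate, atoms) {
  sp <- mixture$species[mixture$species$substrate == substrate, , drop = FALSE]
  if (nrow(sp) == 0) stop("mixture has no species for substrate ", substrate)
  atoms <- as.integer(atoms)
  if (any(atoms < 1)) stop("atom positions must be >= 1")
  out <- numeric(length(atoms) + 1)
  for (k in seq_len(nrow(sp))) {
    p <- ifelse(atoms %in% sp$positions[[k]], sp$purity[k], mixture$natural_abundance)
    out <- out + sp$fraction[k] * mdv_from_probs(p)
  }
  out
}
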