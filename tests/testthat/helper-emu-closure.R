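# Independent EMU dependency-closure oracle: a plain recursive reachability
# computation over (metabolite, atom-set) pairs, working directly on the
# atom-map strings.  Used to cross-check the size of the compiled EMU system.

emu_closure_ids <- function(network, targets) {
  seen <- new.env(parent = emptyenv())
  queue <- list()
  push <- function(met, atoms) {
    atoms <- sort(atoms)
    id <- paste0(met, "|", paste(atoms, collapse = ","))
    if (!exists(id, seen)) {
      assign(id, TRUE, seen)
      if (!met %in% network$inputs)
        queue[[length(queue) + 1]] <<- list(met = met, atoms = atoms)
    }
  }
  for (fr in targets) for (p in fr$parts) push(p$met, p$atoms)
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  while (length(queue)) {
    e <- queue[[1]]; queue[[1]] <- NULL
    for (rx in network$reactions) {
      if (is.null(rx$amap)) next
      sides <- list(list(r = rx$lhs$met, ra = rx$amap$lhs,
                         p = rx$rhs$met, pa = rx$amap$rhs))
      if (rx$reversible)
        sides <- c(sides, list(list(r = rx$rhs$met, ra = rx$amap$rhs,
                                    p = rx$lhs$met, pa = rx$amap$lhs)))
      for (sd in sides) {
        for (occ in which(sd$p == e$met)) {
          letters <- strsplit(sd$pa[occ], "")[[1]][e$atoms]
          # all orientation variants of symmetric reactants
          variant_atoms <- list(sd$ra)
          for (j in which(sd$r %in% network$symmetric)) {
            variant_atoms <- unlist(lapply(variant_atoms, function(va) {
              flipped <- va; flipped[j] <- rev_str(va[j])
              list(va, flipped)
            }), recursive = FALSE)
          }
          for (va in unique(variant_atoms)) {
            for (j in seq_along(sd$r)) {
              pos <- which(strsplit(va[j], "")[[1]] %in% letters)
              if (length(pos)) push(sd$r[j], pos)
            }
          }
        }
      }
    }
  }
  sort(ls(seen))
}
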