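#' Theoretical b/y fragment ions of a peptidoform
#'
#' Generates b(1..n-1) and y(1..n-1) ions at the requested charges.
#' Site-modification deltas are included in every ion that spans the
#' modified position; the heavy C-terminal label mass is included in all
#' y ions (and the precursor), never in b ions.
#'
#' @param p A [peptidoform()].
#' @param charges Integer vector of fragment charges (default 1).
#' @return data.frame with columns `ion` (e.g. `"b3"`, `"y7"`), `type`,
#'   `index`, `charge`, `mz`.
#' @export
theoretical_fragments <- function(p, charges = 1L) {
  stopifnot(inherits(p, "peptidoform"))
  n <- length(p$residues)
  if (n < 2) stop("peptide must have length >= 2")
  res_mass <- RESIDUE_MASS[p$residues]
  mod_mass <- numeric(n)
  for (pos in names(p$site_mods))
    mod_mass[as.integer(pos)] <- p$site_mods[[pos]]$delta_mass
  cum <- cumsum(res_mass + mod_mass)
  water <- monoisotopic_mass(composition(H = 2, O = 1))
  label <- p$c_term_heavy_O * (ATOMIC_MASS[["O18"]] - ATOMIC_MASS[["O"]])
  idx <- seq_len(n - 1)
  b_neutral <- cum[idx]                       # acylium-type neutral
  y_neutral <- cum[n] - cum[n - idx] + water + label
  out <- do.call(rbind, lapply(as.integer(charges), function(z) {
    data.frame(
      ion = c(paste0("b", idx), paste0("y", idx)),
      type = rep(c("b", "y"), each = n - 1),
      index = c(idx, idx), charge = z,
      mz = c((b_neutral + z * PROTON_MASS) / z,
             (y_neutral + z * PROTON_MASS) / z))
  }))
  rownames(out) <- NULL
  out
}

#' Theoretical fragments of a crosslinked species
#'
#' For each chain, b/y ions as for a linear peptide; any fragment that
#' spans the linked residue additionally carries the entire mass of the
#' partner peptide plus the crosslinker delta (the partner appears as a
#' modification mass on the requisite fragment).  Fragments that do not
#' span the link are identical to plain linear fragments.
#'
#' @param x A [crosslink_species()].
#' @param charges Integer vector of fragment charges (default 1).
#' @return data.frame with columns `chain` (`"A"`/`"B"`), `ion`, `type`,
#'   `index`, `charge`, `mz`, `carries_crosslink`.
#' @export
crosslink_fragments <- function(x, charges = 1L) {
  stopifnot(inherits(x, "crosslink_species"))
  delta <- x$crosslinker$delta_mass
  one_chain <- function(chain, p, site, partner_mass) {
    fr <- theoretical_fragments(p, charges)
    n <- length(p$residues)
    spans <- ifelse(fr$type == "b", fr$index >= site, fr$index >= n - site + 1)
    fr$mz <- fr$mz + ifelse(spans, (partner_mass + delta) / fr$charge, 0)
    fr$chain <- chain
    fr$carries_crosslink <- spans
    fr
  }
  out <- rbind(
    one_chain("A", x$alpha, x$donor_site, monoisotopic_mass(x$beta)),
    one_chain("B", x$beta, x$acceptor_site, monoisotopic_mass(x$alpha)))
  out[, c("chain", "ion", "type", "index", "charge", "mz",
          "carries_crosslink")]
}
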