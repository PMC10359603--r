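# Formal net charge and sliding-window charge profiles of protein
# domains. Purely compositional: integer formal charges, no pKa model.

#' Charge rule for formal net-charge accounting
#'
#' Default per-residue charges: Arg +1, Lys +1, Asp -1, Glu -1, His 0
#' (an Arg/Asp/Glu tally such as a DUF2285 domain's +7 = 15 - 6 - 1 - 1
#' counts no His). Terminal contributions (+1 for a free N-terminus,
#' -1 for a free C-terminus) are opt-in, since a domain cut from a
#' larger protein has neither.
#'
#' @param charges named numeric of per-residue charges; letters not
#'   named carry charge 0.
#' @param count_n_terminus,count_c_terminus whether to add the +1 / -1
#'   terminal charge.
#' @return object of class `charge_rule`.
#' @export
charge_rule <- function(charges = c(R = 1, K = 1, D = -1, E = -1, H = 0),
                        count_n_terminus = FALSE, count_c_terminus = FALSE) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(names(charges) %in% aa20))
    stop("charges may only name standard amino-acid letters")
  full <- setNames(rep(0, 20L), aa20)
  full[names(charges)] <- charges
  structure(list(charges = full, count_n_terminus = count_n_terminus,
                 count_c_terminus = count_c_terminus),
            class = "charge_rule")
}

residue_charges <- function(sequence, rule) {
  sequence <- toupper(trimws(sequence))
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(rule$charges))
  if (length(bad) > 0L)
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1L]],
                 bad[1L]))
  unname(rule$charges[res])
}

#' Formal net charge of a protein sequence
#'
#' Sum of per-residue formal charges plus terminal contributions per
#' the rule. For example, a domain of composition 15 Arg / 6 Asp /
#' 1 Glu with a counted free C-terminus has net charge
#' 15 - 6 - 1 - 1 = +7.
#'
#' @param sequence protein sequence over the 20-letter alphabet.
#' @param rule a [charge_rule()].
#' @return integer-valued net charge.
#' @export
#' @examples
#' net_charge("RRRDDE", charge_rule(count_c_terminus = TRUE))
net_charge <- function(sequence, rule = charge_rule()) {
  z <- sum(residue_charges(sequence, rule))
  if (rule$count_n_terminus) z <- z + 1
  if (rule$count_c_terminus) z <- z - 1
  z
}

#' Sliding-window net-charge profile
#'
#' One value per window start; terminal contributions are applied only
#' in the windows that contain a true terminus (the first window for
#' the N-terminus, the last for the C-terminus).
#'
#' @inheritParams net_charge
#' @param window window width in residues (`1 <= window <= length`).
#' @return data.frame with `start` (1-based window start) and `charge`.
#' @export
window_profile <- function(sequence, window, rule = charge_rule()) {
  if (length(window) != 1L || !is.finite(window) || window <= 0)
    stop("window must be a positive count")
  z <- residue_charges(sequence, rule)
  n <- length(z)
  if (window > n) stop("window must be <= sequence length")
  cz <- cumsum(c(0, z))
  starts <- seq_len(n - window + 1L)
  val <- cz[starts + window] - cz[starts]
  if (rule$count_n_terminus) val[1L] <- val[1L] + 1
  if (rule$count_c_terminus) val[length(val)] <- val[length(val)] - 1
  data.frame(start = starts, charge = val)
}
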