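#' Describe a (multi-chain) peptide system
#'
#' Defines the peptide whose dimerization is being analysed: the default
#' arguments describe the amyloid-beta 12-24 fragment (VHHQKLVFFAEDV,
#' Abeta numbering 12-24) studied as a capped homodimer.
#'
#' @param sequence one-letter amino-acid string (canonical residues only).
#' @param first_residue_number residue number of the first residue
#'   (Abeta numbering; 12 for VHHQKLVFFAEDV).
#' @param n_chains number of identical chains (>= 1); 2 for a dimer.
#' @param capping `"ace_nme"` for N-terminal acetyl / C-terminal
#'   N-methylamide caps (termini contribute no charge) or `"none"` for
#'   free zwitterionic termini (+1/-1 per chain).
#' @return An object of class `"peptide_spec"`.
#' @examples
#' ab <- peptide_spec()            # the Abeta12-24 dimer
#' net_charge(ab, assign_charge_states(2.9))
#' @export
peptide_spec <- function(sequence = "VHHQKLVFFAEDV",
                         first_residue_number = 12L,
                         n_chains = 2L,
                         capping = c("ace_nme", "none")) {
  capping <- match.arg(capping)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1)
    stop("'sequence' must be a non-empty one-letter amino-acid string")
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% names(.aa1to3)))
    stop("non-canonical residue letter(s): ",
         paste(unique(res[!res %in% names(.aa1to3)]), collapse = ", "))
  if (n_chains < 1) stop("'n_chains' must be >= 1")
  structure(list(sequence = paste(res, collapse = ""),
                 residues = res,
                 resno = seq.int(first_residue_number,
                                 length.out = length(res)),
                 first_residue_number = as.integer(first_residue_number),
                 n_chains = as.integer(n_chains),
                 capping = capping),
            class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("peptide_spec: %s (residues %d-%d) x %d chain(s), capping=%s\n",
              x$sequence, min(x$resno), max(x$resno), x$n_chains, x$capping))
  invisible(x)
}

#' pH-dependent side-chain charge states
#'
#' Returns the integer charge carried by each titratable residue type in
#' one of three pH bands. The bands reproduce the three simulated
#' conditions (pH 2.9, 5.0 and 8.4): below pH 4 Asp/Glu are protonated
#' (neutral) and His is +1; between pH 4 and 6.5 Asp/Glu are deprotonated
#' (-1) while His remains +1; at and above pH 6.5 His is also neutral.
#' Lys is +1 throughout. The band boundaries sit midway between the
#' relevant side-chain pKa values (Asp/Glu ~3.9-4.1, His ~6.0).
#'
#' @param pH numeric in (0, 14).
#' @return An object of class `"charge_model"`: list with `pH` and
#'   `charges`, a named integer vector over `HIS`, `GLU`, `ASP`, `LYS`,
#'   `other`.
#' @examples
#' assign_charge_states(2.9)$charges
#' @export
assign_charge_states <- function(pH) {
  if (!is.numeric(pH) || length(pH) != 1L || !is.finite(pH) ||
      pH <= 0 || pH >= 14)
    stop("'pH' must be a single value in (0, 14)")
  charges <- if (pH < 4) {
    c(HIS = 1L, GLU = 0L, ASP = 0L, LYS = 1L, other = 0L)
  } else if (pH < 6.5) {
    c(HIS = 1L, GLU = -1L, ASP = -1L, LYS = 1L, other = 0L)
  } else {
    c(HIS = 0L, GLU = -1L, ASP = -1L, LYS = 1L, other = 0L)
  }
  structure(list(pH = pH, charges = charges), class = "charge_model")
}

#' @export
print.charge_model <- function(x, ...) {
  cat(sprintf("charge_model @ pH %.2f: %s\n", x$pH,
              paste(names(x$charges), x$charges, sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' Net charge of a peptide system
#'
#' Sums the per-residue side-chain charges over all chains. Capped
#' (ACE/NME) termini contribute nothing; uncapped termini contribute
#' +1 (N) and -1 (C) per chain, net zero, for pH well between the
#' terminal pKa values (2.29 and 9.74) — which covers the 2.9-8.4 range
#' modelled here.
#'
#' @param spec a [peptide_spec()].
#' @param model a [assign_charge_states()] result.
#' @return integer net charge.
#' @export
net_charge <- function(spec, model) {
  stopifnot(inherits(spec, "peptide_spec"), inherits(model, "charge_model"))
  type <- .aa1to3[spec$residues]
  per_res <- model$charges[ifelse(type %in% c("HIS", "GLU", "ASP", "LYS"),
                                  type, "other")]
  as.integer(sum(per_res) * spec$n_chains)
}

#' Neutralizing monovalent counterion count
#'
#' The simulation box is neutralized with monovalent counterions only:
#' chloride for a positively charged solute, sodium for a negative one.
#'
#' @inheritParams net_charge
#' @return list with `species` (`"anion"`, `"cation"` or `"none"`) and
#'   integer `count` = |net charge|.
#' @examples
#' counterion_count(peptide_spec(), assign_charge_states(2.9))  # 6 anions
#' @export
counterion_count <- function(spec, model) {
  q <- net_charge(spec, model)
  list(species = if (q > 0) "anion" else if (q < 0) "cation" else "none",
       count = abs(q))
}

#' Temperature ladder for replica exchange
#'
#' @param temperatures strictly increasing positive temperatures (K).
#' @param exchange_interval time between exchange attempts (ps); for the
#'   toy Monte Carlo engine this is interpreted as sweeps between
#'   attempts.
#' @return An object of class `"temperature_ladder"`.
#' @export
temperature_ladder <- function(temperatures, exchange_interval = 2) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 1 || any(!is.finite(temperatures)) ||
      any(temperatures <= 0))
    stop("temperatures must be positive and finite")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (exchange_interval <= 0) stop("'exchange_interval' must be > 0")
  structure(list(temperatures = temperatures,
                 exchange_interval = exchange_interval),
            class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("temperature_ladder: %d temperatures, %.2f-%.2f K, exchange every %g\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures), x$exchange_interval))
  invisible(x)
}

#' Geometric temperature ladder
#'
#' Fallback ladder with constant temperature ratio,
#' `T_i = t_min * (t_max/t_min)^(i/(n-1))`; endpoints are exact. Explicit
#' ladders from a dedicated predictor (e.g. the 64-temperature ladder
#' shipped in `inst/extdata/ladder_ab12-24_64.txt`) are accepted as
#' first-class inputs via [read_ladder()].
#'
#' @param t_min,t_max endpoint temperatures (K), `0 < t_min < t_max`.
#' @param n number of temperatures (>= 2).
#' @param exchange_interval passed to [temperature_ladder()].
#' @return A [temperature_ladder()].
#' @export
geometric_ladder <- function(t_min, t_max, n, exchange_interval = 2) {
  if (n < 2) stop("'n' must be >= 2")
  if (!(t_min > 0 && t_max > t_min)) stop("need 0 < t_min < t_max")
  i <- seq.int(0L, n - 1L)
  temps <- t_min * (t_max / t_min)^(i / (n - 1))
  temps[1] <- t_min; temps[n] <- t_max
  temperature_ladder(temps, exchange_interval)
}

#' Read / write plain-text ladder files (one temperature per line, K)
#'
#' @param path file path.
#' @param exchange_interval passed to [temperature_ladder()].
#' @return [read_ladder()] returns a [temperature_ladder()];
#'   [write_ladder()] returns `path` invisibly.
#' @export
read_ladder <- function(path, exchange_interval = 2) {
  x <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  temperature_ladder(x, exchange_interval)
}

#' @rdname read_ladder
#' @param ladder a [temperature_ladder()].
#' @export
write_ladder <- function(ladder, path) {
  stopifnot(inherits(ladder, "temperature_ladder"))
  writeLines(sprintf("%.2f", ladder$temperatures), path)
  invisible(path)
}

#' The packaged 64-temperature replica ladder (315.00-513.54 K)
#'
#' Convenience accessor for the ladder used in the reference REMD
#' protocol for the Abeta12-24 dimer in explicit water (64 replicas,
#' exchange attempts every 2 ps, ~30% mean acceptance).
#'
#' @param exchange_interval passed to [temperature_ladder()].
#' @return A [temperature_ladder()] of length 64.
#' @export
ab_ladder64 <- function(exchange_interval = 2) {
  read_ladder(system.file("extdata", "ladder_ab12-24_64.txt",
                          package = "dimerscope", mustWork = TRUE),
              exchange_interval)
}
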