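#' Analytic one-dimensional model potentials
#'
#' Stand-ins for the explicit-solvent system, used by the toy
#' replica-exchange engine and the Boltzmann distance sampler.
#'
#' * `harmonic`: `V(x) = 0.5 * k * (x - x0)^2`, parameters `k`
#'   (kJ/mol/nm^2) and `x0` (nm).
#' * `double_well`: `V(x) = barrier * ((x - x0)^2/halfsep^2 - 1)^2`,
#'   parameters `barrier` (kJ/mol), `halfsep` (nm, half the minima
#'   separation) and `x0` (nm, barrier-top location): two minima at
#'   `x0 +- halfsep`, barrier height `barrier` at `x0`.
#' * `custom`: any vectorized function `V(x)` in kJ/mol.
#'
#' @param kind `"harmonic"`, `"double_well"` or `"custom"`.
#' @param parameters named list (see above); for `custom`, an element
#'   `fun`.
#' @return An object of class `"model_potential"`; callable via
#'   [potential_energy()].
#' @examples
#' dw <- model_potential("double_well",
#'                       list(barrier = 12, halfsep = 0.4, x0 = 0.9))
#' potential_energy(dw, c(0.5, 0.9, 1.3))   # 0, 12, 0
#' @export
model_potential <- function(kind = c("harmonic", "double_well", "custom"),
                            parameters = list()) {
  kind <- match.arg(kind)
  p <- parameters
  fun <- switch(kind,
    harmonic = {
      k <- if (is.null(p$k)) 100 else p$k
      x0 <- if (is.null(p$x0)) 0 else p$x0
      p$k <- k; p$x0 <- x0
      function(x) 0.5 * k * (x - x0)^2
    },
    double_well = {
      barrier <- if (is.null(p$barrier)) 12 else p$barrier
      halfsep <- if (is.null(p$halfsep)) 0.4 else p$halfsep
      x0 <- if (is.null(p$x0)) 0 else p$x0
      p$barrier <- barrier; p$halfsep <- halfsep; p$x0 <- x0
      function(x) barrier * (((x - x0) / halfsep)^2 - 1)^2
    },
    custom = {
      if (!is.function(p$fun)) stop("custom potential needs 'fun'")
      p$fun
    })
  structure(list(kind = kind, parameters = p, fun = fun),
            class = "model_potential")
}

#' @rdname model_potential
#' @param potential a `model_potential`.
#' @param x coordinate(s), nm.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "model_potential"))
  v <- potential$fun(x)
  if (any(!is.finite(v) & is.finite(x)))
    stop("potential returned non-finite energy on finite input")
  v
}

#' Replica-exchange acceptance probability
#'
#' The Metropolis criterion for swapping configurations between two
#' replicas: `p = min(1, exp(Delta))` with
#' `Delta = (beta_i - beta_j) * (E_i - E_j)`, where `beta = 1/(kB T)` and
#' `i` is conventionally the colder replica (larger beta).
#'
#' @param beta_i,beta_j inverse temperatures, mol/kJ.
#' @param E_i,E_j potential energies of the configurations currently at
#'   the two temperatures, kJ/mol.
#' @return list with `delta` and `p` (the acceptance probability).
#' @examples
#' exchange_probability(0.4, 0.3, 5, 10)$p  # exp(-0.5)
#' @export
exchange_probability <- function(beta_i, beta_j, E_i, E_j) {
  if (!all(is.finite(c(beta_i, beta_j, E_i, E_j))))
    stop("non-finite energy or inverse temperature")
  delta <- (beta_i - beta_j) * (E_i - E_j)
  list(delta = delta, p = min(1, exp(delta)))
}

#' Run the toy replica-exchange Monte Carlo engine
#'
#' Each replica performs Metropolis Monte Carlo with Gaussian proposals
#' on a one-dimensional model potential at its current temperature;
#' every `exchange_interval` sweeps, configuration swaps between
#' neighbouring temperatures are attempted with the Metropolis exchange
#' criterion, alternating deterministically between the even and odd
#' neighbour pairs. Per-temperature coordinate marginals are therefore
#' exactly Boltzmann in the long run, which makes the engine a testable
#' stand-in for a molecular-dynamics REMD run.
#'
#' @param potential a [model_potential()].
#' @param ladder a [temperature_ladder()]; its `exchange_interval` is the
#'   number of MC sweeps between exchange attempts.
#' @param n_steps number of MC sweeps (>= 1).
#' @param seed integer RNG seed (recorded in the result).
#' @param step_size Gaussian proposal standard deviation (nm); default
#'   scales with temperature as `0.3*sqrt(kB*T)` per replica, which keeps
#'   within-replica acceptance near 40% for the bundled potentials.
#' @param x0 initial coordinate(s), recycled over replicas.
#' @return An object of class `"replica_ensemble"`: list with `ladder`,
#'   `seed`, `steps` (data.frame: step, replica, temp_index, coord,
#'   energy; one row per replica per sweep) and `exchanges` (data.frame:
#'   step, pair, delta, accepted). `replica` identifies the walker,
#'   `temp_index` the ladder rung it currently occupies; at every step
#'   the replica-to-temperature map is a permutation.
#' @export
run_toy_remd <- function(potential, ladder, n_steps, seed = 1L,
                         step_size = NULL, x0 = 0) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(ladder, "temperature_ladder"))
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  temps <- ladder$temperatures
  n_rep <- length(temps)
  if (n_rep < 1) stop("empty ladder")
  kB <- phys_const$kB
  beta <- 1 / (kB * temps)
  if (is.null(step_size)) step_size <- 0.3 * sqrt(kB * temps)
  step_size <- rep(step_size, length.out = n_rep)
  interval <- max(1L, as.integer(round(ladder$exchange_interval)))

  set.seed(as.integer(seed))
  # state indexed by temperature slot: coordinate and which replica sits there
  x <- rep(as.numeric(x0), length.out = n_rep)
  rep_at <- seq_len(n_rep)              # temperature slot -> replica id
  E <- potential_energy(potential, x)

  coord_log <- matrix(NA_real_, n_steps, n_rep)
  energy_log <- matrix(NA_real_, n_steps, n_rep)
  replica_log <- matrix(NA_integer_, n_steps, n_rep)
  ex_step <- integer(0); ex_pair <- integer(0)
  ex_delta <- numeric(0); ex_acc <- logical(0)
  phase <- 0L

  for (s in seq_len(n_steps)) {
    prop <- x + stats::rnorm(n_rep, 0, step_size)
    Ep <- potential_energy(potential, prop)
    acc <- log(stats::runif(n_rep)) < -beta * (Ep - E)
    x[acc] <- prop[acc]; E[acc] <- Ep[acc]
    if (n_rep > 1 && s %% interval == 0L) {
      lo <- if (1L + phase <= n_rep - 1L)
        seq.int(1L + phase, n_rep - 1L, by = 2L) else integer(0)
      for (i in lo) {
        ex <- exchange_probability(beta[i], beta[i + 1], E[i], E[i + 1])
        ok <- stats::runif(1) < ex$p
        if (ok) {
          x[c(i, i + 1)] <- x[c(i + 1, i)]
          E[c(i, i + 1)] <- E[c(i + 1, i)]
          rep_at[c(i, i + 1)] <- rep_at[c(i + 1, i)]
        }
        ex_step <- c(ex_step, s); ex_pair <- c(ex_pair, i)
        ex_delta <- c(ex_delta, ex$delta); ex_acc <- c(ex_acc, ok)
      }
      phase <- 1L - phase
    }
    coord_log[s, ] <- x; energy_log[s, ] <- E; replica_log[s, ] <- rep_at
  }

  steps <- data.frame(
    step = rep(seq_len(n_steps), each = n_rep),
    replica = as.integer(t(replica_log)),
    temp_index = rep(seq_len(n_rep), times = n_steps),
    coord = as.numeric(t(coord_log)),
    energy = as.numeric(t(energy_log)))
  exchanges <- data.frame(step = ex_step, pair = ex_pair,
                          delta = ex_delta, accepted = ex_acc)
  structure(list(ladder = ladder, potential = potential,
                 seed = as.integer(seed), steps = steps,
                 exchanges = exchanges),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat(sprintf(
    "replica_ensemble: %d replicas x %d sweeps, %d exchange attempts (%.1f%% accepted), seed %d\n",
    length(x$ladder$temperatures), max(x$steps$step), nrow(x$exchanges),
    if (nrow(x$exchanges)) 100 * mean(x$exchanges$accepted) else NA_real_,
    x$seed))
  invisible(x)
}

#' Mean exchange acceptance for a neighbour pair
#'
#' @param ensemble a [run_toy_remd()] result.
#' @param pair integer: attempts between temperature slots `pair` and
#'   `pair + 1`; `NULL` averages over all pairs.
#' @return acceptance fraction in \[0, 1\].
#' @export
mean_acceptance <- function(ensemble, pair = NULL) {
  stopifnot(inherits(ensemble, "replica_ensemble"))
  ex <- ensemble$exchanges
  if (!is.null(pair)) ex <- ex[ex$pair == pair, , drop = FALSE]
  if (nrow(ex) == 0) {
    warning("no exchange attempts logged for this pair")
    return(NA_real_)
  }
  mean(ex$accepted)
}

#' Write / read a toy-REMD run as self-describing TSV tables
#'
#' Two files are produced: `<stem>_steps.tsv` and `<stem>_exchanges.tsv`,
#' each with a `# key: value` provenance header (potential, ladder,
#' seed).
#'
#' @param ensemble a [run_toy_remd()] result.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_remd_tables <- function(ensemble, stem) {
  stopifnot(inherits(ensemble, "replica_ensemble"))
  hdr <- c(sprintf("# potential: %s", ensemble$potential$kind),
           sprintf("# parameters: %s",
                   paste(names(ensemble$potential$parameters),
                         vapply(ensemble$potential$parameters,
                                function(p) if (is.function(p)) "<fun>"
                                            else format(p), ""),
                         sep = "=", collapse = " ")),
           sprintf("# ladder_K: %s",
                   paste(sprintf("%.2f", ensemble$ladder$temperatures),
                         collapse = ",")),
           sprintf("# seed: %d", ensemble$seed))
  for (what in c("steps", "exchanges")) {
    path <- paste0(stem, "_", what, ".tsv")
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(
      ensemble[[what]], path, sep = "\t", quote = FALSE,
      row.names = FALSE, append = TRUE))
  }
  invisible(stem)
}
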