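# Discrete-state folding models: the generating process behind simulated
# smFRET traces.  States are ordered along the folding pathway
# ssRNA -> G-hairpin -> G-triplex -> G4, with FRET emission means increasing
# with the degree of folding.

.check_stochastic <- function(P, tol = 1e-12) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(P)) || any(P < 0)) {
    stop("transition matrix entries must be finite and non-negative",
         call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    stop("transition matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  invisible(P)
}

.default_state_labels <- function(k) {
  switch(as.character(k),
    "2" = c("ssRNA", "G4"),
    "3" = c("ssRNA", "G-hairpin", "G-triplex"),
    "4" = c("ssRNA", "G-hairpin", "G-triplex", "G4"),
    paste0("state_", seq_len(k))
  )
}

#' Define a discrete-state folding model
#'
#' A folding model couples a per-frame Markov chain over folding states to
#' Gaussian FRET emissions.  States are ordered by folding progress, so
#' `emission_means` must be strictly increasing: the lowest-FRET state is the
#' unfolded single strand and the highest-FRET state the fully folded
#' quadruplex, with G-hairpin and G-triplex intermediates in between.
#'
#' @param emission_means Per-state mean FRET efficiency, strictly increasing,
#'   all in `[0, 1]`.
#' @param emission_sds Per-state FRET standard deviation (> 0).  A scalar is
#'   recycled.
#' @param transition_matrix Row-stochastic per-frame transition matrix over
#'   the states (rows sum to 1 within `1e-12`).
#' @param initial_distribution Probability vector over states at frame 1.
#'   Defaults to the stationary distribution of `transition_matrix` when the
#'   chain is irreducible, otherwise uniform.
#' @param state_labels Optional state names; sensible folding-pathway labels
#'   are supplied for 2-4 states.
#'
#' @return An object of class `folding_model`: a list with elements
#'   `state_labels`, `emission_means`, `emission_sds`, `transition_matrix`,
#'   `initial_distribution`.
#' @seealso [sticky_birth_death()], [atrg3_model()], [g4_model()],
#'   [potassium_transition_matrix()]
#' @export
#' @examples
#' m <- atrg3_model()
#' m$emission_means
folding_model <- function(emission_means, emission_sds, transition_matrix,
                          initial_distribution = NULL, state_labels = NULL) {
  k <- length(emission_means)
  if (k < 1) stop("at least one state is required", call. = FALSE)
  if (any(emission_means < 0 | emission_means > 1)) {
    stop("emission_means must lie in [0, 1]", call. = FALSE)
  }
  if (k > 1 && any(diff(emission_means) <= 0)) {
    stop("emission_means must be strictly increasing with folding order",
         call. = FALSE)
  }
  emission_sds <- rep_len(emission_sds, k)
  if (any(emission_sds <= 0)) stop("emission_sds must be > 0", call. = FALSE)
  .check_stochastic(transition_matrix)
  if (nrow(transition_matrix) != k) {
    stop("transition_matrix dimension does not match the number of states",
         call. = FALSE)
  }
  if (is.null(initial_distribution)) {
    initial_distribution <- tryCatch(
      stationary_distribution(transition_matrix),
      error = function(e) rep(1 / k, k)
    )
  }
  if (length(initial_distribution) != k ||
      any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-12) {
    stop("initial_distribution must be a length-K probability vector",
         call. = FALSE)
  }
  structure(
    list(
      state_labels = state_labels %||% .default_state_labels(k),
      emission_means = as.numeric(emission_means),
      emission_sds = as.numeric(emission_sds),
      transition_matrix = unname(transition_matrix),
      initial_distribution = as.numeric(initial_distribution)
    ),
    class = "folding_model"
  )
}

#' @export
print.folding_model <- function(x, ...) {
  k <- length(x$emission_means)
  cat("<folding_model> ", k, " states\n", sep = "")
  df <- data.frame(
    state = x$state_labels,
    mean = x$emission_means,
    sd = x$emission_sds,
    initial = round(x$initial_distribution, 4)
  )
  print(df, row.names = FALSE)
  cat("transition matrix (per frame):\n")
  print(round(x$transition_matrix, 4))
  invisible(x)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves \eqn{\pi P = \pi}, \eqn{\sum_i \pi_i = 1} for an irreducible chain.
#' Used to express equilibrium folding-state occupancies implied by a
#' transition matrix.
#'
#' @param transition_matrix A square row-stochastic matrix (or a
#'   [folding_model()], whose matrix is used).
#' @return A probability vector `pi` with `pi %*% P == pi`.
#' @export
#' @examples
#' stationary_distribution(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
stationary_distribution <- function(transition_matrix) {
  P <- transition_matrix
  if (inherits(P, "folding_model")) P <- P$transition_matrix
  .check_stochastic(P)
  k <- nrow(P)
  if (k == 1L) return(1)
  # Reachability closure: the set reachable from any state is closed, so a
  # proper subset witnesses reducibility.
  reach <- (P > 0) | diag(TRUE, k)
  for (i in seq_len(ceiling(log2(k)) + 1L)) {
    reach <- (reach %*% reach) > 0
  }
  if (!all(reach)) {
    sizes <- rowSums(reach)
    cls <- which(reach[which.min(sizes), ])
    stop("reducible chain: states {", paste(cls, collapse = ", "),
         "} form an absorbing class", call. = FALSE)
  }
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Sticky birth-death transition matrix
#'
#' Builds the default chain topology of the folding pathway: transitions only
#' between adjacent states, each state keeping probability `self_prob` per
#' frame and splitting the remainder between its neighbours (all of it to the
#' single neighbour at the ends).
#'
#' @param k Number of states.
#' @param self_prob Per-frame probability of staying in the current state.
#' @return A `k x k` row-stochastic matrix.
#' @export
sticky_birth_death <- function(k, self_prob = 0.95) {
  stopifnot(k >= 1, self_prob >= 0, self_prob <= 1)
  P <- diag(rep(self_prob, k))
  if (k == 1L) return(matrix(1, 1, 1))
  move <- 1 - self_prob
  for (i in seq_len(k)) {
    nb <- intersect(c(i - 1L, i + 1L), seq_len(k))
    P[i, nb] <- move / length(nb)
  }
  P
}

#' Three-state model of the ATRG3 mutant
#'
#' The ATRG3 construct (the ATR quadruplex with its last G-column mutated)
#' can only reach the G-hairpin and G-triplex intermediates, giving three
#' FRET states at means 0.32, 0.50 and 0.74.  The chain is a sticky
#' birth-death over ssRNA <-> G-hairpin <-> G-triplex.
#'
#' @param self_prob Per-frame self-transition probability (default 0.95).
#' @param emission_sds Per-state FRET s.d. (default 0.06).
#' @return A [folding_model()] with 3 states.
#' @export
atrg3_model <- function(self_prob = 0.95, emission_sds = 0.06) {
  folding_model(
    emission_means = c(0.32, 0.50, 0.74),
    emission_sds = emission_sds,
    transition_matrix = sticky_birth_death(3, self_prob),
    state_labels = c("ssRNA", "G-hairpin", "G-triplex")
  )
}

#' Four-state model of a full three-layer quadruplex
#'
#' Extends [atrg3_model()] with the well-folded G4 state at FRET ~0.92
#' (the 3G(ATR)-style construct), over the full pathway
#' ssRNA <-> G-hairpin <-> G-triplex <-> G4.
#'
#' @inheritParams atrg3_model
#' @return A [folding_model()] with 4 states.
#' @export
g4_model <- function(self_prob = 0.95, emission_sds = 0.06) {
  folding_model(
    emission_means = c(0.32, 0.50, 0.74, 0.92),
    emission_sds = emission_sds,
    transition_matrix = sticky_birth_death(4, self_prob)
  )
}

#' Potassium-dependent birth-death transition matrix
#'
#' Folding of G-quadruplexes is driven by K+ coordination between quartets;
#' higher KCl shifts occupancy toward the folded state.  The K+ -> rate
#' mapping is a modelling stand-in (no kinetic rates are available for these
#' constructs): all forward (folding) transition probabilities are scaled by
#' a Hill factor \eqn{c^h / (c^h + K_{1/2}^h)} of the KCl concentration,
#' with a small floor keeping the chain irreducible, while unfolding rates
#' are concentration-independent.  Two-layer quadruplexes need higher K+ to
#' fold, which is expressed as a larger `k_half`.
#'
#' @param model A [folding_model()] (for its state count) or an integer
#'   number of states.
#' @param kcl_mM KCl concentration in mM (>= 0).
#' @param k_half Half-saturation KCl concentration in mM (default 30,
#'   a three-layer-like value; use larger values for two-layer constructs).
#' @param hill Hill coefficient of the K+ dependence (default 2).
#' @param fold_max Maximal per-frame folding probability at saturating K+.
#' @param fold_min Folding-probability floor at 0 mM (keeps the chain
#'   irreducible; the unfolded state still dominates).
#' @param unfold Per-frame unfolding probability (K+-independent).
#' @return A row-stochastic matrix whose stationary folded-state occupancy is
#'   non-decreasing in `kcl_mM` and negligible at 0 mM.
#' @export
#' @examples
#' P0 <- potassium_transition_matrix(4, 0)
#' P150 <- potassium_transition_matrix(4, 150)
#' stationary_distribution(P150)
potassium_transition_matrix <- function(model, kcl_mM, k_half = 30, hill = 2,
                                        fold_max = 0.15, fold_min = 1e-4,
                                        unfold = 0.05) {
  k <- if (inherits(model, "folding_model")) length(model$emission_means)
       else as.integer(model)
  if (!is.finite(kcl_mM) || kcl_mM < 0) {
    stop("kcl_mM must be a non-negative concentration", call. = FALSE)
  }
  stopifnot(k >= 2, fold_max + unfold <= 1, fold_min <= fold_max)
  sat <- if (kcl_mM == 0) 0 else kcl_mM^hill / (kcl_mM^hill + k_half^hill)
  p_fold <- fold_min + (fold_max - fold_min) * sat
  P <- matrix(0, k, k)
  for (i in seq_len(k)) {
    if (i < k) P[i, i + 1L] <- p_fold
    if (i > 1) P[i, i - 1L] <- unfold
    P[i, i] <- 1 - sum(P[i, ])
  }
  P
}

#' Potassium-conditioned folding model
#'
#' Convenience wrapper combining the default four-state (or `ATRG3`
#' three-state) emission model with [potassium_transition_matrix()] at a
#' given KCl concentration.
#'
#' @param kcl_mM KCl concentration in mM.
#' @param construct `"3G"` (full three-layer quadruplex, 4 states),
#'   `"ATRG3"` (3 states), or `"2G"` (two-layer; 4 states with a larger
#'   `k_half`, reflecting that two-layer quadruplexes fold only at higher
#'   K+).
#' @param emission_sds Per-state FRET s.d.
#' @param ... Passed on to [potassium_transition_matrix()].
#' @return A [folding_model()] whose initial distribution is the stationary
#'   distribution at that concentration.
#' @export
potassium_model <- function(kcl_mM, construct = c("3G", "ATRG3", "2G"),
                            emission_sds = 0.06, ...) {
  construct <- match.arg(construct)
  means <- switch(construct,
    "3G" = c(0.32, 0.50, 0.74, 0.92),
    "ATRG3" = c(0.32, 0.50, 0.74),
    "2G" = c(0.35, 0.55, 0.78, 0.95)
  )
  args <- list(...)
  if (construct == "2G" && is.null(args$k_half)) args$k_half <- 150
  P <- do.call(potassium_transition_matrix,
               c(list(model = length(means), kcl_mM = kcl_mM), args))
  folding_model(means, emission_sds, P,
                initial_distribution = stationary_distribution(P))
}

#' Helicase-unwinding (non-equilibrium) model
#'
#' Represents the situation after injecting an ATP-driven quadruplex helicase:
#' folding transitions are switched off and only stepwise unfolding along the
#' pathway remains, so the chain drains toward the unfolded state.  Traces are
#' started from the equilibrium occupancy of `base` (the pre-injection
#' condition), so pooled frames show the folded fraction decreasing and the
#' unfolded fraction increasing.
#'
#' @param base The equilibrium [folding_model()] describing the condition
#'   before helicase injection.
#' @param unfold Per-frame unfolding probability under helicase action.
#' @return A [folding_model()] with a reducible (absorbing at ssRNA)
#'   transition matrix and the base model's stationary occupancy as initial
#'   distribution.
#' @export
unwinding_model <- function(base, unfold = 0.05) {
  stopifnot(inherits(base, "folding_model"))
  k <- length(base$emission_means)
  P <- diag(1, k)
  for (i in seq_len(k)[-1L]) {
    P[i, i - 1L] <- unfold
    P[i, i] <- 1 - unfold
  }
  init <- tryCatch(stationary_distribution(base$transition_matrix),
                   error = function(e) base$initial_distribution)
  folding_model(base$emission_means, base$emission_sds, P,
                initial_distribution = init,
                state_labels = base$state_labels)
}
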