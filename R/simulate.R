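#' Specify a synthetic balanced split-plot activity experiment
#'
#' Describes a balanced `g x e x r` design with additive block, genotype
#' and environment effects, an optional doubly-centered low-rank
#' interaction, and the two Gaussian error strata of a split-plot layout:
#' a main-plot error (SD `sigma_main`) drawn once per (environment,
#' block) pair and shared by all genotypes measured in that main plot,
#' and an independent sub-plot error (SD `sigma_sub`) per observation.
#'
#' The defaults mirror a five-temperature, six-block enzyme-activity
#' trial with four assayed factors, on the scale of muscle antioxidant
#' activities (units of U/mg): `mu = 10`, `sigma_block = 0.2`,
#' `sigma_main = 0.3`, `sigma_sub = 0.64`.
#'
#' @param g,e,r numbers of genotypes, environments and blocks.
#' @param mu grand mean.
#' @param genotype_effects zero-sum g-vector (default all zero).
#' @param environment_effects zero-sum e-vector (default all zero).
#' @param interaction doubly-centered `g x e` matrix (default all zero).
#' @param sigma_block,sigma_main,sigma_sub non-negative SDs of the block
#'   effects, the main-plot errors, and the sub-plot errors.
#' @param genotype_labels,environment_labels,block_labels optional label
#'   vectors (defaults `G1..`, `E1..`, `B1..`).
#' @param units unit string carried into the simulated table.
#' @return An object of class `sim_spec` (a validated list).
#' @seealso [simulate_activity()], [make_effects_for_target_ss()]
#' @export
sim_spec <- function(g = 4L, e = 5L, r = 6L, mu = 10,
                     genotype_effects = NULL, environment_effects = NULL,
                     interaction = NULL,
                     sigma_block = 0.2, sigma_main = 0.3, sigma_sub = 0.64,
                     genotype_labels = NULL, environment_labels = NULL,
                     block_labels = NULL, units = "U/mg") {
  g <- as.integer(g); e <- as.integer(e); r <- as.integer(r)
  if (any(is.na(c(g, e, r))) || g < 1L || e < 1L || r < 1L)
    stop("g, e, r must be positive integers")
  if (is.null(genotype_effects)) genotype_effects <- numeric(g)
  if (is.null(environment_effects)) environment_effects <- numeric(e)
  if (is.null(interaction)) interaction <- matrix(0, g, e)
  interaction <- as.matrix(interaction)
  if (length(genotype_effects) != g || length(environment_effects) != e ||
      !all(dim(interaction) == c(g, e)))
    stop("effect dimensions must match g and e")
  ctol <- 1e-10 * max(1, max(abs(genotype_effects)), max(abs(environment_effects)),
                      max(abs(interaction)))
  if (abs(sum(genotype_effects)) > ctol || abs(sum(environment_effects)) > ctol)
    stop("genotype_effects and environment_effects must each sum to zero")
  if (any(abs(rowSums(interaction)) > ctol) || any(abs(colSums(interaction)) > ctol))
    stop("interaction matrix must be doubly centered (zero row and column sums)")
  if (sigma_block < 0 || sigma_main < 0 || sigma_sub < 0)
    stop("error SDs must be non-negative")
  lab <- function(given, prefix, n) {
    if (is.null(given)) return(paste0(prefix, seq_len(n)))
    if (length(given) != n || anyDuplicated(given))
      stop("labels must be unique and of the right length")
    as.character(given)
  }
  structure(list(g = g, e = e, r = r, mu = mu,
                 genotype_effects = genotype_effects,
                 environment_effects = environment_effects,
                 interaction = interaction,
                 sigma_block = sigma_block, sigma_main = sigma_main,
                 sigma_sub = sigma_sub,
                 genotype_labels = lab(genotype_labels, "G", g),
                 environment_labels = lab(environment_labels, "E", e),
                 block_labels = lab(block_labels, "B", r),
                 units = units),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("Simulation spec: %d x %d x %d design, mu = %g\n", x$g, x$e, x$r, x$mu))
  cat(sprintf("SDs: block %g, main-plot %g, sub-plot %g\n",
              x$sigma_block, x$sigma_main, x$sigma_sub))
  cat(sprintf("effect norms: genotype %.4g, environment %.4g, interaction %.4g (Frobenius)\n",
              sqrt(sum(x$genotype_effects^2)), sqrt(sum(x$environment_effects^2)),
              sqrt(sum(x$interaction^2))))
  invisible(x)
}

#' Simulate a balanced activity table from a specification
#'
#' Draws \eqn{y_{gep} = \mu + b_p + \rho_g + \psi_e + \omega_{ge} +
#' h_{ep} + \varepsilon_{gep}} with independent Gaussian block effects
#' \eqn{b_p}, main-plot errors \eqn{h_{ep}} (one draw per (environment,
#' block) pair, shared across genotypes), and sub-plot errors per
#' observation.  A fixed seed yields a bit-identical table; the RNG
#' state of the session is left untouched.
#'
#' @param spec a [sim_spec()].
#' @param seed optional integer seed.
#' @return An [activity_table()].
#' @export
simulate_activity <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  g <- spec$g; e <- spec$e; r <- spec$r
  b <- stats::rnorm(r, 0, spec$sigma_block)
  h <- matrix(stats::rnorm(e * r, 0, spec$sigma_main), e, r)
  eps <- array(stats::rnorm(g * e * r, 0, spec$sigma_sub), dim = c(g, e, r))

  idx <- expand.grid(gi = seq_len(g), ei = seq_len(e), pi = seq_len(r))
  val <- spec$mu + b[idx$pi] + spec$genotype_effects[idx$gi] +
    spec$environment_effects[idx$ei] +
    spec$interaction[cbind(idx$gi, idx$ei)] +
    h[cbind(idx$ei, idx$pi)] + eps[cbind(idx$gi, idx$ei, idx$pi)]
  activity_table(genotype = spec$genotype_labels[idx$gi],
                 environment = spec$environment_labels[idx$ei],
                 block = spec$block_labels[idx$pi],
                 value = val, units = spec$units,
                 genotype_order = spec$genotype_labels,
                 environment_order = spec$environment_labels,
                 block_order = spec$block_labels)
}

#' Build a specification whose expected SS shares hit given targets
#'
#' Inverse design for parameter-recovery studies: given target
#' percentages of the *total* sum of squares for the genotype,
#' environment and interaction rows of the AMMI ANOVA, scales fixed
#' deterministic effect patterns so that the expected SS decomposition
#' matches the targets.  Under the generating model the expectations in
#' a balanced `g x e x r` design are
#'
#' \deqn{E[SS_G] = er\sum\rho_g^2 + (g-1)\sigma^2}
#' \deqn{E[SS_E] = gr\sum\psi_e^2 + (e-1)(g\sigma_h^2 + \sigma^2)}
#' \deqn{E[SS_{GE}] = r\sum\omega_{ge}^2 + (g-1)(e-1)\sigma^2}
#' \deqn{E[SS_{tot}] = er\sum\rho^2 + gr\sum\psi^2 + r\sum\omega^2 +
#'   ge(r-1)\sigma_b^2 + g(er-1)\sigma_h^2 + (ger-1)\sigma^2}
#'
#' (block effects and main-plot errors cancel from the genotype margin;
#' main-plot errors enter the environment margin through the shared
#' main-plot draws).  Solving these linear relations for the three
#' effect magnitudes is closed-form; infeasible targets — negative
#' implied effect SS, or shares summing to 1 or more — are an error.
#'
#' Effect patterns are deterministic: centered linear contrasts for the
#' genotype and environment vectors and their unit-Frobenius rank-1
#' outer product for the interaction, so the planted interaction loads a
#' single IPCA axis.
#'
#' @param g,e,r design sizes.
#' @param target_pcts numeric length-3 vector: percentages of total SS
#'   for (genotype, environment, interaction); must sum to < 100.
#' @param mu,sigma_block,sigma_main,sigma_sub passed to [sim_spec()].
#' @return A [sim_spec()] meeting the targets in expectation.
#' @examples
#' spec <- make_effects_for_target_ss(4, 5, 6, c(85.2102, 4.1430, 8.4604))
#' @export
make_effects_for_target_ss <- function(g, e, r, target_pcts, mu = 10,
                                       sigma_block = 0.2, sigma_main = 0.3,
                                       sigma_sub = 0.64) {
  g <- as.integer(g); e <- as.integer(e); r <- as.integer(r)
  if (length(target_pcts) != 3L || any(target_pcts < 0))
    stop("target_pcts must be 3 non-negative percentages (genotype, environment, interaction)")
  p <- target_pcts / 100
  if (sum(p) >= 1) stop("target percentages must sum to < 100")
  s2 <- sigma_sub^2; sh2 <- sigma_main^2; sb2 <- sigma_block^2
  n_g <- (g - 1) * s2
  n_e <- (e - 1) * (g * sh2 + s2)
  n_i <- (g - 1) * (e - 1) * s2
  n_tot <- g * e * (r - 1) * sb2 + g * (e * r - 1) * sh2 + (g * e * r - 1) * s2
  tot <- (n_tot - n_g - n_e - n_i) / (1 - sum(p))
  A <- p[1] * tot - n_g
  B <- p[2] * tot - n_e
  C <- p[3] * tot - n_i
  if (min(A, B, C) < -1e-9 * max(1, tot))
    stop("infeasible targets: a requested share is below the noise floor of that row")
  A <- max(A, 0); B <- max(B, 0); C <- max(C, 0)
  contrast <- function(n) {
    v <- seq_len(n) - (n + 1) / 2
    v / sqrt(sum(v^2))
  }
  rho <- sqrt(A / (e * r)) * contrast(g)
  psi <- sqrt(B / (g * r)) * contrast(e)
  omega <- sqrt(C / r) * outer(contrast(g), contrast(e))
  sim_spec(g = g, e = e, r = r, mu = mu,
           genotype_effects = rho, environment_effects = psi,
           interaction = omega,
           sigma_block = sigma_block, sigma_main = sigma_main,
           sigma_sub = sigma_sub)
}

#' Expected AMMI sums of squares under a specification
#'
#' Closed-form expectations used by [make_effects_for_target_ss()]; also
#' handy for checking the generator against Monte-Carlo averages.
#'
#' @param spec a [sim_spec()].
#' @return Named numeric vector with components `genotype`,
#'   `environment`, `interaction`, `total`.
#' @export
expected_ss <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  g <- spec$g; e <- spec$e; r <- spec$r
  s2 <- spec$sigma_sub^2; sh2 <- spec$sigma_main^2; sb2 <- spec$sigma_block^2
  A <- e * r * sum(spec$genotype_effects^2)
  B <- g * r * sum(spec$environment_effects^2)
  C <- r * sum(spec$interaction^2)
  c(genotype = A + (g - 1) * s2,
    environment = B + (e - 1) * (g * sh2 + s2),
    interaction = C + (g - 1) * (e - 1) * s2,
    total = A + B + C + g * e * (r - 1) * sb2 + g * (e * r - 1) * sh2 +
      (g * e * r - 1) * s2)
}
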