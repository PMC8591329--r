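#' @importFrom stats rnorm rbinom rpois runif
NULL

# Draw n rows from N(0, Sigma) via eigendecomposition (tolerates a
# singular, merely positive-semidefinite Sigma).
.rmvn <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values))))
    stop("covariance matrix is not positive semidefinite", call. = FALSE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% t(A)
}

#' Uniform (flat or shared) fitness regime across tactics
#'
#' Convenience constructor for the `selection` field of [sim_config()]:
#' the same log-fitness coefficients for all three tactics.  The default
#' (`b1 = b2 = 0`) is the flat-fitness regime used for estimator
#' calibration, where reproductive success is independent of length.
#'
#' @param b0 intercept of log mean reproductive success.
#' @param b1,b2 linear and quadratic coefficients on within-tactic
#'   standardized length.
#' @return Named list of per-tactic `c(b0, b1, b2)` vectors.
#' @export
uniform_selection <- function(b0 = log(2.5), b1 = 0, b2 = 0) {
  one <- c(b0 = b0, b1 = b1, b2 = b2)
  list(female = one, hooknose = one, jack = one)
}

#' Configuration of the synthetic two-generation pedigree
#'
#' Defaults emulate a small wild coho population monitored at a weir over
#' two generations: 301 dams and 322 sires (18% jacks) returning in
#' 2002-2003, 775
#' offspring returning in 2004-2006; tactic length means 733 (female), 735
#' (hooknose) and 423 mm (jack); phenotypic SDs anchored at 48 mm for
#' females and set so the hooknose:female variance ratio is 1/0.415 and
#' the hooknose:jack ratio 2.77; per-tactic heritabilities 0.36/0.87/0.47;
#' no intertactical genetic correlation (`r_G` identity); male-tactic
#' liability heritability 0.9; and tactic-specific log-linear fitness
#' coefficients matching the observed pooled gradients and mean
#' reproductive successes (2.61/2.80/1.21).
#'
#' @param n_dams,n_sires founder counts.
#' @param jack_fraction target fraction of jacks among sires (liability
#'   threshold is the matching normal quantile).
#' @param n_offspring offspring count.
#' @param tactic_means_mm,tactic_sd_mm named numeric vectors
#'   (female/hooknose/jack) of phenotypic means and SDs of length (mm).
#' @param h2 named vector of per-tactic narrow-sense heritabilities in
#'   `[0, 1]`.
#' @param r_G 3x3 genetic correlation matrix of the tactic-specific
#'   expressions of length (order female, hooknose, jack; unit diagonal,
#'   positive semidefinite).
#' @param tactic_liability_h2 heritability of the male-tactic liability in
#'   `[0, 1]`.
#' @param selection named list (female/hooknose/jack) of `c(b0, b1, b2)`:
#'   log mean reproductive success is `b0 + b1 x + b2 x^2` with x the
#'   within-tactic standardized length.  See [uniform_selection()].
#' @param parent_years,offspring_years integer return years of the two
#'   generations (all parent years must precede all offspring years).
#' @param seed integer seed used by [simulate_pedigree()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_dams = 301, n_sires = 322, jack_fraction = 0.18,
                       n_offspring = 775,
                       tactic_means_mm = c(female = 733, hooknose = 735,
                                           jack = 423),
                       tactic_sd_mm = c(female = 48,
                                        hooknose = 48 / sqrt(0.415),
                                        jack = 48 / sqrt(0.415 * 2.77)),
                       h2 = c(female = 0.36, hooknose = 0.87, jack = 0.47),
                       r_G = diag(3), tactic_liability_h2 = 0.9,
                       selection = list(
                         female = c(b0 = log(2.61), b1 = 0.142, b2 = -0.019),
                         hooknose = c(b0 = log(2.80), b1 = 0.239, b2 = 0.004),
                         jack = c(b0 = log(1.21), b1 = 0.098, b2 = 0.043)),
                       parent_years = c(2002L, 2003L),
                       offspring_years = 2004:2006, seed = 1L) {
  stopifnot(n_dams >= 1, n_sires >= 1, n_offspring >= 1)
  if (jack_fraction <= 0 || jack_fraction >= 1)
    stop("jack_fraction must be in (0, 1)", call. = FALSE)
  for (v in list(tactic_means_mm, tactic_sd_mm, h2))
    if (!all(TACTICS %in% names(v)))
      stop("tactic-indexed fields need names female/hooknose/jack",
           call. = FALSE)
  if (any(tactic_sd_mm <= 0)) stop("SDs must be positive", call. = FALSE)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must be in [0, 1]", call. = FALSE)
  if (tactic_liability_h2 < 0 || tactic_liability_h2 > 1)
    stop("tactic_liability_h2 must be in [0, 1]", call. = FALSE)
  r_G <- as.matrix(r_G)
  if (!all(dim(r_G) == c(3, 3)) || any(abs(diag(r_G) - 1) > 1e-12) ||
      any(abs(r_G - t(r_G)) > 1e-12))
    stop("r_G must be a symmetric 3x3 correlation matrix", call. = FALSE)
  if (any(eigen(r_G, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("r_G is not positive semidefinite", call. = FALSE)
  if (!all(TACTICS %in% names(selection)))
    stop("selection needs entries female/hooknose/jack", call. = FALSE)
  if (max(parent_years) >= min(offspring_years))
    stop("parent years must precede offspring years", call. = FALSE)
  structure(list(n_dams = as.integer(n_dams), n_sires = as.integer(n_sires),
                 jack_fraction = jack_fraction,
                 n_offspring = as.integer(n_offspring),
                 tactic_means_mm = tactic_means_mm[TACTICS],
                 tactic_sd_mm = tactic_sd_mm[TACTICS],
                 h2 = h2[TACTICS], r_G = r_G,
                 tactic_liability_h2 = tactic_liability_h2,
                 selection = selection[TACTICS],
                 parent_years = as.integer(parent_years),
                 offspring_years = as.integer(offspring_years),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# 4x4 breeding-value covariance: the three tactic-specific expressions of
# length (correlation r_G) plus an independent liability component.
.sigma_g <- function(cfg) {
  S <- diag(4)
  S[1:3, 1:3] <- cfg$r_G
  S
}

# phenotype = mu_t + h_t * sd_t * a_t + e,  var(e) = (1 - h2_t) sd_t^2
.express_length <- function(tactic, A, cfg) {
  idx <- match(tactic, TACTICS)
  a_expr <- A[cbind(seq_along(tactic), idx)]
  h2 <- cfg$h2[idx]
  sd_p <- cfg$tactic_sd_mm[idx]
  unname(cfg$tactic_means_mm[idx] + sqrt(h2) * sd_p * a_expr +
           stats::rnorm(length(tactic), 0, sqrt(pmax(1 - h2, 0)) * sd_p))
}

# liability-threshold male tactic: jack iff liability exceeds the
# (1 - jack_fraction) normal quantile
.male_tactic <- function(a_L, cfg) {
  h2L <- cfg$tactic_liability_h2
  L <- sqrt(h2L) * a_L + sqrt(1 - h2L) * stats::rnorm(length(a_L))
  ifelse(L > stats::qnorm(1 - cfg$jack_fraction), "jack", "hooknose")
}

.latent_names <- c("a_f", "a_h", "a_j", "a_L")

# sample() guarding against the scalar-first-argument expansion
.sample_vec <- function(x, n) {
  if (length(x) == 1) rep(x, n) else sample(x, n, replace = TRUE)
}

#' Simulate the founder (parent) generation
#'
#' Founder breeding-value vectors are drawn from a zero-mean multivariate
#' normal with the configured correlation structure; males are assigned
#' jack or hooknose by the liability threshold; phenotypes follow the
#' additive model `length = mu_t + sqrt(h2_t) sd_t a_t + e`.  The caller
#' manages the RNG state (see [simulate_pedigree()] for the seeded entry
#' point).
#'
#' @param cfg a [sim_config()].
#' @return Data frame of founders with pedigree columns plus latent
#'   breeding values `a_f`, `a_h`, `a_j`, `a_L`; `rs` is `NA` until
#'   [assign_fitness()].
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_dams + cfg$n_sires
  A <- .rmvn(n, .sigma_g(cfg))
  colnames(A) <- .latent_names
  sex <- rep(c("female", "male"), c(cfg$n_dams, cfg$n_sires))
  tactic <- character(n)
  tactic[sex == "female"] <- "female"
  tactic[sex == "male"] <- .male_tactic(A[sex == "male", "a_L"], cfg)
  d <- data.frame(
    id = c(sprintf("D%04d", seq_len(cfg$n_dams)),
           sprintf("S%04d", seq_len(cfg$n_sires))),
    sex = sex, tactic = tactic,
    year = .sample_vec(cfg$parent_years, n),
    length_mm = .express_length(tactic, A, cfg),
    rs = NA_integer_, dam_id = NA_character_, sire_id = NA_character_,
    generation = "parent", stringsAsFactors = FALSE)
  cbind(d, as.data.frame(A))
}

#' Draw reproductive success from the tactic-specific fitness model
#'
#' Within each tactic, length is standardized to that tactic's sample mean
#' and SD and reproductive success is drawn Poisson with
#' `log(mean) = b0 + b1 x + b2 x^2`.
#'
#' @param records data frame with `tactic` and `length_mm` (e.g. from
#'   [simulate_founders()]).
#' @param cfg a [sim_config()].
#' @return `records` with `rs` filled in (nonnegative integers).
#' @export
assign_fitness <- function(records, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (t in unique(records$tactic)) {
    i <- which(records$tactic == t)
    len <- records$length_mm[i]
    s <- if (length(i) > 1) stats::sd(len) else 0
    x <- if (is.finite(s) && s > 0) (len - mean(len)) / s else rep(0, length(i))
    b <- cfg$selection[[t]]
    records$rs[i] <- stats::rpois(length(i),
                                  exp(b[["b0"]] + b[["b1"]] * x +
                                        b[["b2"]] * x^2))
  }
  records
}

#' Mate founders and breed the offspring generation
#'
#' Each offspring draws a dam with probability proportional to dam
#' reproductive success and a sire proportional to sire reproductive
#' success.  Offspring breeding values are the parental mean plus a
#' Mendelian-segregation deviate with half the population breeding-value
#' covariance, so offspring breeding-value variance equals the founder
#' variance.  Sex is Bernoulli(1/2) with no genetic basis; male tactic
#' follows the liability rule; phenotypes follow the additive model.  The
#' emitted parental `rs` is the *realized* offspring count (the number of
#' their offspring present in the pedigree), matching the
#' offspring-that-returned semantics of the fitness measure; offspring
#' `rs` is drawn from the fitness model.
#'
#' @param parents founders with `rs` assigned (used as mating weights).
#' @param cfg a [sim_config()].
#' @return List with `parents` (rs replaced by realized counts) and
#'   `offspring` (data frame with latent breeding values).
#' @export
mate_and_breed <- function(parents, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dams <- parents[parents$sex == "female", , drop = FALSE]
  sires <- parents[parents$sex == "male", , drop = FALSE]
  if (!nrow(dams) || !nrow(sires))
    stop("need at least one dam and one sire", call. = FALSE)
  if (sum(dams$rs) == 0 || sum(sires$rs) == 0)
    stop("all candidate parents have zero reproductive success",
         call. = FALSE)
  n <- cfg$n_offspring
  di <- sample(nrow(dams), n, replace = TRUE, prob = dams$rs)
  si <- sample(nrow(sires), n, replace = TRUE, prob = sires$rs)
  Ad <- as.matrix(dams[di, .latent_names])
  As <- as.matrix(sires[si, .latent_names])
  A <- 0.5 * (Ad + As) + .rmvn(n, 0.5 * .sigma_g(cfg))
  colnames(A) <- .latent_names
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "female", "male")
  tactic <- character(n)
  tactic[sex == "female"] <- "female"
  tactic[sex == "male"] <- .male_tactic(A[sex == "male", "a_L"], cfg)
  off <- data.frame(
    id = sprintf("O%05d", seq_len(n)),
    sex = sex, tactic = tactic,
    year = .sample_vec(cfg$offspring_years, n),
    length_mm = .express_length(tactic, A, cfg),
    rs = NA_integer_,
    dam_id = dams$id[di], sire_id = sires$id[si],
    generation = "offspring", stringsAsFactors = FALSE)
  off <- assign_fitness(cbind(off, as.data.frame(A)), cfg)
  realized <- table(c(off$dam_id, off$sire_id))
  parents$rs <- as.integer(realized[parents$id])
  parents$rs[is.na(parents$rs)] <- 0L
  list(parents = parents, offspring = off)
}

#' Simulate a two-generation tactic-structured pedigree
#'
#' Seeded end-to-end driver: founders are simulated, given fitness (the
#' mating propensity), mated and bred; the combined two-generation table is
#' validated through [as_pedigree()].  Deterministic given `cfg$seed`
#' (single Mersenne-Twister stream seeded once at entry, inversion normals).
#'
#' @param cfg a [sim_config()].
#' @param latent if `TRUE`, attach the latent breeding-value table
#'   (id plus `a_f`, `a_h`, `a_j`, `a_L`) as attribute `"latent"` for
#'   oracle tests.
#' @return A validated pedigree of `n_dams + n_sires + n_offspring` rows.
#' @export
simulate_pedigree <- function(cfg = sim_config(), latent = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  founders <- assign_fitness(simulate_founders(cfg), cfg)
  gen2 <- mate_and_breed(founders, cfg)
  all <- rbind(gen2$parents, gen2$offspring)
  ped <- as_pedigree(all[, setdiff(names(all), .latent_names)])
  if (latent)
    attr(ped, "latent") <- all[, c("id", .latent_names)]
  ped
}
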