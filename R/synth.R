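# Synthetic fixtures: networks, annotations, age universes, survival cohorts ---

#' Named toy networks
#'
#' Small topologies with known dynamics:
#' \describe{
#'   \item{self_activator}{one node with an activating self-edge; under the
#'     default parameters its stable fixed points are 0 and (1+sqrt(5))/4.}
#'   \item{toggle}{two mutually inhibiting nodes (a bistable toggle switch).}
#'   \item{bax_motif}{the five-node pro-apoptotic motif: BAX activated by
#'     c-Myc and p53, inhibited by Bcl-2 and Bcl-xL.}
#'   \item{no_edges}{three isolated nodes (each relaxes to tau under the
#'     constitutive convention).}
#'   \item{random}{Erdos-Renyi-style signed digraph: each ordered node pair
#'     (self-loops included) carries an edge with probability `density`,
#'     activating with probability `activation_fraction`.}
#' }
#'
#' @param name One of `"self_activator"`, `"toggle"`, `"bax_motif"`,
#'   `"no_edges"`, `"random"`.
#' @param n_nodes,density,activation_fraction Random-network parameters.
#' @param seed RNG seed for `"random"`.
#' @return An [network()] object.
#' @export
make_toy_network <- function(name = c("self_activator", "toggle", "bax_motif",
                                      "no_edges", "random"),
                             n_nodes = 10, density = 0.3,
                             activation_fraction = 0.6, seed = NULL) {
  name <- match.arg(name)
  switch(
    name,
    self_activator = network(
      data.frame(id = "A"),
      data.frame(source = "A", target = "A", sign = "activation")
    ),
    toggle = network(
      data.frame(id = c("A", "B")),
      data.frame(source = c("A", "B"), target = c("B", "A"),
                 sign = "inhibition")
    ),
    bax_motif = network(
      data.frame(id = c("BAX", "c-Myc", "p53", "Bcl-2", "Bcl-xL"),
                 module = c("apoptosis", "other", "other", "other", "other")),
      data.frame(source = c("c-Myc", "p53", "Bcl-2", "Bcl-xL"),
                 target = "BAX",
                 sign = c("activation", "activation",
                          "inhibition", "inhibition"))
    ),
    no_edges = network(data.frame(id = c("A", "B", "C"))),
    random = {
      if (!is.null(seed)) set.seed(seed)
      stopifnot(n_nodes >= 1, density >= 0, density <= 1)
      ids <- sprintf("n%02d", seq_len(n_nodes))
      pairs <- expand.grid(source = ids, target = ids,
                           stringsAsFactors = FALSE)
      keep <- stats::runif(nrow(pairs)) < density
      edges <- pairs[keep, , drop = FALSE]
      if (nrow(edges)) {
        edges$sign <- ifelse(stats::runif(nrow(edges)) < activation_fraction,
                             "activation", "inhibition")
      } else {
        edges <- NULL
      }
      network(data.frame(id = ids), edges)
    }
  )
}

#' Synthetic expression-change annotations
#'
#' Emulates an annotated differential-expression table: per node, with
#' probability `p_agree` the annotation equals the simulated direction (cancer
#' vs normal attractor), otherwise one of the two other labels uniformly at
#' random.
#'
#' @param cancer,normal Attractors (or named activity vectors) over the same
#'   network.
#' @param p_agree Probability that a node's annotation matches its simulated
#'   direction.
#' @param tol Unchanged band passed to [simulated_direction()].
#' @param dataset Dataset label written into the table.
#' @param seed RNG seed.
#' @return Annotation data frame (`node`, `dataset`, `direction`).
#' @export
make_annotations <- function(cancer, normal, p_agree = 0.8, tol = 0.1,
                             dataset = "synthetic", seed = NULL) {
  stopifnot(p_agree >= 0, p_agree <= 1)
  if (!is.null(seed)) set.seed(seed)
  sim <- simulated_direction(cancer, normal, tol = tol)
  agree <- stats::runif(length(sim)) < p_agree
  direction <- vapply(seq_along(sim), function(i) {
    if (agree[i]) sim[i] else sample(setdiff(.DIRECTIONS, sim[i]), 1)
  }, character(1))
  data.frame(node = names(sim), dataset = dataset, direction = direction,
             stringsAsFactors = FALSE)
}

#' Synthetic gene-age universe with planted driver enrichment
#'
#' Builds a gene universe whose strata are drawn with the given weights, then
#' samples a driver set with a `fold`-times higher sampling weight for genes of
#' the planted stratum (`fold = 1` plants no signal).
#'
#' @param universe_size Number of genes in the universe.
#' @param weights Eight per-stratum sampling weights (recycled if a scalar).
#' @param driver_count Number of driver genes to sample (without replacement).
#' @param planted Stratum receiving the enrichment.
#' @param fold Multiplicative sampling weight for planted-stratum genes
#'   (>= 1).
#' @param seed RNG seed.
#' @return List with `ages` (named character, gene -> stratum) and `drivers`
#'   (character vector).
#' @export
make_age_universe <- function(universe_size = 1000, weights = 1,
                              driver_count = 200, planted = "eumetazoa",
                              fold = 5, seed = NULL) {
  stopifnot(universe_size >= 1, fold >= 1)
  if (driver_count <= 0) stop("driver_count must be positive")
  if (driver_count > universe_size) {
    stop("driver_count cannot exceed universe_size")
  }
  planted <- as.character(as_age_class(planted))
  if (!is.null(seed)) set.seed(seed)
  weights <- rep_len(weights, length(.AGE_CLASSES))
  genes <- sprintf("g%05d", seq_len(universe_size))
  strata <- sample(.AGE_CLASSES, universe_size, replace = TRUE,
                   prob = weights / sum(weights))
  ages <- stats::setNames(strata, genes)
  w <- ifelse(strata == planted, fold, 1)
  drivers <- sample(genes, driver_count, prob = w)
  list(ages = ages, drivers = drivers)
}

# Censoring rate c for independent exponential censoring such that the expected
# censored fraction over the cohort's hazards equals `target`.
.censoring_rate <- function(hazard, target) {
  if (target <= 0) return(0)
  if (target >= 1) stop("censoring fraction must be < 1")
  f <- function(cc) mean(cc / (cc + hazard)) - target
  stats::uniroot(f, lower = 1e-10, upper = 1e10, tol = 1e-12)$root
}

#' Synthetic train/test survival cohorts with a planted gene signature
#'
#' Expression is standard normal per gene and sample. The event hazard is
#' proportional-hazards: `baseline * exp(sum_g beta_g * x_g)` over the planted
#' signal genes, whose age strata are drawn from `allowed_strata`. Optional
#' decoy genes emulate passenger associations: they carry a hazard effect in
#' the training cohort only (their association does not reproduce in the test
#' cohort) and their strata are drawn from outside `allowed_strata`. Event
#' times are exponential given the per-sample hazard; censoring is independent
#' exponential with its rate tuned so the expected censored fraction equals
#' `censoring`.
#'
#' @param n_train,n_test Cohort sizes.
#' @param n_genes Total genes (signal + decoy + noise).
#' @param n_signal Number of planted signal genes.
#' @param n_decoy Number of training-only passenger genes.
#' @param beta Log-hazard per expression SD of each signal gene (signs
#'   alternate +/-).
#' @param decoy_beta Training-only log-hazard of each decoy gene.
#' @param baseline Baseline hazard rate.
#' @param censoring Expected censored fraction in \[0, 1).
#' @param allowed_strata Strata assigned to signal genes (decoys get the
#'   complement; noise genes get uniform strata).
#' @param seed RNG seed.
#' @return List with `train` and `test` ([survival_dataset()]s), `ages` (named
#'   character for all genes) and `truth` (data frame: gene, role, beta_train,
#'   beta_test, sign).
#' @export
make_survival_cohorts <- function(n_train = 300, n_test = 300, n_genes = 200,
                                  n_signal = 10, n_decoy = 0, beta = 1,
                                  decoy_beta = 1, baseline = 0.1,
                                  censoring = 0.3,
                                  allowed_strata = c("eukaryota",
                                                     "opisthokonta",
                                                     "eumetazoa"),
                                  seed = NULL) {
  stopifnot(n_signal + n_decoy <= n_genes, n_signal >= 0, n_decoy >= 0,
            censoring >= 0, censoring < 1, baseline > 0)
  allowed_strata <- as.character(as_age_class(allowed_strata))
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  role <- rep("noise", n_genes)
  if (n_signal) role[seq_len(n_signal)] <- "signal"
  if (n_decoy) role[n_signal + seq_len(n_decoy)] <- "decoy"

  beta_train <- numeric(n_genes)
  beta_test <- numeric(n_genes)
  if (n_signal) {
    signs <- rep_len(c(1, -1), n_signal)
    beta_train[role == "signal"] <- beta * signs
    beta_test[role == "signal"] <- beta * signs
  }
  if (n_decoy) {
    beta_train[role == "decoy"] <- decoy_beta * rep_len(c(1, -1), n_decoy)
  }

  other <- setdiff(.AGE_CLASSES, allowed_strata)
  strata <- sample(.AGE_CLASSES, n_genes, replace = TRUE)
  strata[role == "signal"] <- sample(allowed_strata, n_signal, replace = TRUE)
  strata[role == "decoy"] <- sample(other, n_decoy, replace = TRUE)
  ages <- stats::setNames(strata, genes)

  simulate_cohort <- function(n, betas, prefix) {
    x <- matrix(stats::rnorm(n_genes * n), nrow = n_genes,
                dimnames = list(genes, sprintf("%s%04d", prefix, seq_len(n))))
    hazard <- baseline * exp(as.vector(crossprod(x, betas)))
    t_event <- stats::rexp(n, rate = hazard)
    if (censoring > 0) {
      cc <- .censoring_rate(hazard, censoring)
      t_cens <- stats::rexp(n, rate = cc)
      survival_dataset(x, pmin(t_event, t_cens),
                       as.integer(t_event <= t_cens))
    } else {
      survival_dataset(x, t_event, rep(1L, n))
    }
  }
  train <- simulate_cohort(n_train, beta_train, "tr")
  test <- simulate_cohort(n_test, beta_test, "te")
  truth <- data.frame(gene = genes, role = role, beta_train = beta_train,
                      beta_test = beta_test,
                      sign = ifelse(beta_train > 0, "positive",
                                    ifelse(beta_train < 0, "negative", "none")),
                      stratum = strata, stringsAsFactors = FALSE)
  list(train = train, test = test, ages = ages, truth = truth)
}
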