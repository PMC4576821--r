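#' Configuration of a simulated screening campaign
#'
#' Defaults mirror the screening campaign being emulated: libraries of 350
#' error-prone PCR variants with a mean of 1.3 amino-acid mutations per
#' gene, ten rounds of best-of-library selection, and exclusion of
#' mutations that revert position 151 to the ancestral nucleophile.
#'
#' The per-mutation activity-effect model is a mixture on the log10 scale:
#' with probability `p_deleterious` a N(`del_mean`, `del_sd`) draw
#' (deleterious/neutral), otherwise an Exponential with mean `ben_mean`
#' (beneficial); effects in the serine and cysteine backgrounds are
#' correlated (`rho`, Gaussian copula) to emulate near-neutrality of the
#' cysteine path.
#'
#' @param library_size variants screened per round (default 350)
#' @param mutation_lambda mean amino-acid mutations per gene (default 1.3,
#'   modelled as Poisson)
#' @param rounds rounds of evolution (default 10)
#' @param revertant_position residue index whose reversion to
#'   `ancestral_residue` is discarded (default 151)
#' @param ancestral_residue the forbidden reversion target (default "C")
#' @param screen_noise_sd screening read-out noise, log10 units (default 0.2)
#' @param p_deleterious,del_mean,del_sd,ben_mean,rho effect-distribution
#'   parameters (defaults 0.7, -0.3, 0.3, 0.3, 0.9)
#' @param gene_length protein length in residues (default 237)
#' @param parent_log10_ser,parent_log10_cys latent parent activities,
#'   log10(min^-1 M^-1) (defaults 0.4 and 4.0: a ~10^3.6-fold nucleophile
#'   handicap at the slow phase)
#' @param readout_mode `"log_activity"` (noisy log10 activity) or
#'   `"endpoint"` (noisy fraction converted at `t_screen` minutes)
#' @param t_screen screening endpoint time, minutes (endpoint mode only)
#' @param seed integer seed
#' @return object of class `screen_config`
#' @export
screen_config <- function(library_size = 350, mutation_lambda = 1.3,
                          rounds = 10, revertant_position = 151,
                          ancestral_residue = "C", screen_noise_sd = 0.2,
                          p_deleterious = 0.7, del_mean = -0.3, del_sd = 0.3,
                          ben_mean = 0.3, rho = 0.9, gene_length = 237,
                          parent_log10_ser = 0.4, parent_log10_cys = 4.0,
                          readout_mode = c("log_activity", "endpoint"),
                          t_screen = 60, seed = 1) {
  readout_mode <- match.arg(readout_mode)
  if (library_size < 1) stop("library_size must be >= 1", call. = FALSE)
  if (rounds < 1) stop("rounds must be >= 1", call. = FALSE)
  if (mutation_lambda < 0) stop("mutation_lambda must be >= 0", call. = FALSE)
  if (screen_noise_sd < 0) stop("screen_noise_sd must be >= 0", call. = FALSE)
  if (rho < -1 || rho > 1) stop("rho must be in [-1, 1]", call. = FALSE)
  if (p_deleterious < 0 || p_deleterious > 1) {
    stop("p_deleterious must be in [0, 1]", call. = FALSE)
  }
  structure(list(library_size = as.integer(library_size),
                 mutation_lambda = mutation_lambda, rounds = as.integer(rounds),
                 revertant_position = as.integer(revertant_position),
                 ancestral_residue = ancestral_residue,
                 screen_noise_sd = screen_noise_sd,
                 p_deleterious = p_deleterious, del_mean = del_mean,
                 del_sd = del_sd, ben_mean = ben_mean, rho = rho,
                 gene_length = as.integer(gene_length),
                 parent_log10_ser = parent_log10_ser,
                 parent_log10_cys = parent_log10_cys,
                 readout_mode = readout_mode, t_screen = t_screen,
                 seed = as.integer(seed)),
            class = "screen_config")
}

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Synthetic handicapped parent variant
#'
#' Builds the round-0 parent of a simulated campaign: a deterministic
#' synthetic protein sequence of `gene_length` residues carrying the
#' nucleophile handicap (`ancestral_residue` at `revertant_position`
#' replaced by Ser), with the configured latent activities. The sequence is
#' synthetic — a repeating amino-acid pattern, not any natural protein.
#'
#' @param config a [screen_config()]
#' @return a `library_variant`: list with `variant_id`, `sequence`,
#'   `mutations` (data frame), `true_log10_activity_ser`,
#'   `true_log10_activity_cys`, `screen_readout`
#' @export
parent_variant <- function(config = screen_config()) {
  seq_chr <- rep_len(AA1, config$gene_length)
  seq_chr[config$revertant_position] <- config$ancestral_residue
  ancestor <- paste(seq_chr, collapse = "")
  seq_chr[config$revertant_position] <- "S"
  structure(list(variant_id = "round0",
                 sequence = paste(seq_chr, collapse = ""),
                 ancestor_sequence = ancestor,
                 mutations = empty_mutation_table(),
                 true_log10_activity_ser = config$parent_log10_ser,
                 true_log10_activity_cys = config$parent_log10_cys,
                 screen_readout = NA_real_),
            class = "library_variant")
}

empty_mutation_table <- function() {
  data.frame(position = integer(0), from_aa = character(0),
             to_aa = character(0), round = character(0),
             kind = character(0), stringsAsFactors = FALSE)
}

# Quantile function of the mixture effect distribution, inverted on a grid.
effect_quantile_fun <- function(config) {
  x <- seq(config$del_mean - 8 * config$del_sd,
           stats::qexp(1 - 1e-9, 1 / config$ben_mean), length.out = 4096)
  cdf <- config$p_deleterious * stats::pnorm(x, config$del_mean, config$del_sd) +
    (1 - config$p_deleterious) * stats::pexp(x, 1 / config$ben_mean)
  function(u) stats::approx(cdf, x, xout = pmin(pmax(u, 1e-9), 1 - 1e-9),
                            rule = 2)$y
}

# Correlated (Gaussian copula) bivariate draws from the mixture marginal:
# one effect per background per mutation.
draw_effects <- function(n, config, qfun) {
  z1 <- stats::rnorm(n)
  z2 <- config$rho * z1 + sqrt(1 - config$rho^2) * stats::rnorm(n)
  data.frame(ser = qfun(stats::pnorm(z1)), cys = qfun(stats::pnorm(z2)))
}

#' Generate one error-prone PCR library
#'
#' Per variant the mutation count is Poisson(`mutation_lambda`), positions
#' are uniform over the gene (distinct within a variant), and the
#' substituted residue is uniform over the 19 alternatives. Mutations that
#' would revert `revertant_position` to `ancestral_residue` are resampled,
#' emulating the discard of nucleophile revertants during screening. Each
#' mutation perturbs both latent log10 activities by correlated draws from
#' the configured effect distribution.
#'
#' @param parent a `library_variant` (see [parent_variant()])
#' @param config a [screen_config()]
#' @param seed integer seed, or `NULL` to draw from the current RNG state
#'   (used internally by [simulate_de()])
#' @param round_label label recorded on new mutations
#' @return list of `library_variant` objects of length
#'   `config$library_size`
#' @export
generate_library <- function(parent, config, seed = config$seed,
                             round_label = "1") {
  draw <- function() {
    qfun <- effect_quantile_fun(config)
    parent_chr <- strsplit(parent$sequence, "")[[1]]
    ancestral <- config$ancestral_residue
    lapply(seq_len(config$library_size), function(i) {
      n_mut <- stats::rpois(1, config$mutation_lambda)
      n_mut <- min(n_mut, config$gene_length)
      seq_chr <- parent_chr
      muts <- empty_mutation_table()
      if (n_mut > 0) {
        pos <- sample.int(config$gene_length, n_mut)
        to <- character(n_mut)
        for (j in seq_len(n_mut)) {
          from <- seq_chr[pos[j]]
          choices <- setdiff(AA1, from)
          if (pos[j] == config$revertant_position) {
            choices <- setdiff(choices, ancestral)  # revertants discarded
          }
          to[j] <- sample(choices, 1)
          seq_chr[pos[j]] <- to[j]
        }
        muts <- data.frame(position = pos, from_aa = parent_chr[pos],
                           to_aa = to, round = round_label, kind = "point",
                           stringsAsFactors = FALSE)
      }
      eff <- draw_effects(n_mut, config, qfun)
      structure(list(variant_id = sprintf("%s_v%03d", round_label, i),
                     sequence = paste(seq_chr, collapse = ""),
                     ancestor_sequence = parent$ancestor_sequence,
                     mutations = rbind(parent$mutations, muts),
                     true_log10_activity_ser =
                       parent$true_log10_activity_ser + sum(eff$ser),
                     true_log10_activity_cys =
                       parent$true_log10_activity_cys + sum(eff$cys),
                     screen_readout = NA_real_),
                class = "library_variant")
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

screen_readout <- function(variant, config) {
  act <- variant$true_log10_activity_ser
  base <- switch(config$readout_mode,
    log_activity = act,
    endpoint = {
      # fraction of substrate converted at t_screen in a 1 uM lysate assay
      kobs <- 10^act * 1e-6  # second-order (min^-1 M^-1) x 1 uM in M
      1 - exp(-kobs * config$t_screen)
    })
  base + stats::rnorm(1, 0, config$screen_noise_sd)
}

#' Simulate a directed-evolution campaign
#'
#' Iterates rounds of library generation from the current best variant,
#' noisy activity screening in the serine background, and carry-forward of
#' the top-ranked variant; the latent activities of both nucleophile
#' backgrounds are recorded every round. With zero screening noise the
#' selected lineage is monotone non-decreasing in true serine activity
#' (unmutated clones re-present the parent in every library).
#'
#' @param config a [screen_config()]
#' @return a `trajectory_table` data frame with columns `round`,
#'   `variant_id`, `n_mutations`, `ser_constant`, `cys_constant` (min^-1
#'   M^-1) and `log10_ser`, `log10_cys`; the selected lineage (list of
#'   `library_variant`) is attached as attribute `"lineage"`.
#' @export
simulate_de <- function(config = screen_config()) {
  withr::with_seed(config$seed, {
    current <- parent_variant(config)
    lineage <- list(current)
    for (r in seq_len(config$rounds)) {
      lib <- generate_library(current, config, seed = NULL,
                              round_label = as.character(r))
      readouts <- vapply(lib, screen_readout, numeric(1), config = config)
      current <- lib[[which.max(readouts)]]
      current$screen_readout <- max(readouts)
      lineage[[r + 1L]] <- current
    }
    tab <- data.frame(
      round = 0:config$rounds,
      variant_id = vapply(lineage, `[[`, character(1), "variant_id"),
      n_mutations = vapply(lineage, function(v) nrow(v$mutations), integer(1)),
      log10_ser = vapply(lineage, `[[`, numeric(1), "true_log10_activity_ser"),
      log10_cys = vapply(lineage, `[[`, numeric(1), "true_log10_activity_cys"),
      stringsAsFactors = FALSE)
    tab$ser_constant <- 10^tab$log10_ser
    tab$cys_constant <- 10^tab$log10_cys
    structure(tab, lineage = lineage,
              class = c("trajectory_table", "data.frame"))
  })
}
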