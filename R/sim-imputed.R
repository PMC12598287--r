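#' Imputation error model
#'
#' Governs how the simulator corrupts truth genotypes into "imputed" calls.
#' The probability that a call is wrong depends on the site's MAF tranche and
#' on the truth genotype class (heterozygous vs homozygous), and decays with
#' sequencing coverage as `exp(-coverage_decay * coverage)` — rarer alleles
#' and heterozygotes impute worse, and accuracy rises with coverage. A wrong
#' heterozygote becomes the homozygote of the panel's major allele; a wrong
#' homozygote becomes a heterozygote with probability 0.8 and the opposite
#' homozygote otherwise, making spurious heterozygotes the dominant error
#' mode. Maximum genotype probabilities for correct and wrong calls are drawn
#' from separate Beta laws (mapped into (0.5, 1) so the GP argmax always
#' equals the emitted genotype), giving GP filters genuine discriminating
#' power.
#'
#' @param p_wrong matrix of baseline error probabilities, rows = tranche
#'   levels of [maf_tranche()] (monomorphic first), columns `het` and `hom`.
#' @param coverage_decay decay constant k in `exp(-k * coverage)`.
#' @param gp_correct,gp_wrong `c(shape1, shape2)` of the Beta law for max-GP
#'   of correct and wrong calls; `gp_correct` must stochastically dominate.
#' @param miss_rate probability a call is dropped to missing outright.
#' @return An `error_model` list.
#' @export
error_model <- function(
    p_wrong = default_p_wrong(),
    coverage_decay = 1.0,
    gp_correct = c(8, 0.4), gp_wrong = c(2, 2),
    miss_rate = 0) {
  stopifnot(all(p_wrong >= 0 & p_wrong <= 1),
            coverage_decay >= 0, miss_rate >= 0, miss_rate <= 1,
            all(gp_correct > 0), all(gp_wrong > 0))
  if (gp_correct[1] / sum(gp_correct) <= gp_wrong[1] / sum(gp_wrong))
    stop("gp_correct must have larger mean than gp_wrong")
  structure(list(p_wrong = p_wrong, coverage_decay = coverage_decay,
                 gp_correct = gp_correct, gp_wrong = gp_wrong,
                 miss_rate = miss_rate),
            class = "error_model")
}

#' @rdname error_model
#' @export
default_p_wrong <- function() {
  tr <- levels(maf_tranche(0))
  m <- cbind(het = c(0.02, 0.25, 0.18, 0.10, 0.05, 0.03, 0.02),
             hom = c(0.01, 0.10, 0.07, 0.04, 0.02, 0.012, 0.008))
  rownames(m) <- tr
  m
}

#' Simulate an imputed callset from truth under an error model
#'
#' @param truth truth [new_callset()] (no GP needed).
#' @param model an [error_model()].
#' @param coverage sequencing coverage (x-fold) used for the decay term.
#' @param seed integer seed.
#' @return A callset with GP triples; class `callset`.
#' @export
simulate_imputed <- function(truth, model, coverage, seed = 1L) {
  stopifnot(inherits(model, "error_model"), coverage > 0)
  sites <- truth$sites
  n <- nrow(sites)
  tranche <- as.character(maf_tranche(sites$maf))
  if (!all(tranche %in% rownames(model$p_wrong)))
    stop("unknown tranche in error model: ",
         paste(setdiff(tranche, rownames(model$p_wrong)), collapse = ", "))
  alt_major <- if ("alt_freq" %in% names(sites)) sites$alt_freq > 0.5
               else rep(FALSE, n)
  major_hom <- ifelse(alt_major, 2L, 0L)

  with_seed(seed, {
    d_true <- truth$dosage
    cls <- ifelse(d_true == 1L, "het", "hom")
    p_eff <- pmin(1, model$p_wrong[cbind(tranche, cls)] *
                    exp(-model$coverage_decay * coverage))
    p_eff[is.na(d_true)] <- 0
    wrong <- stats::runif(n) < p_eff
    d_imp <- d_true
    # wrong het -> major-allele homozygote
    wh <- wrong & d_true == 1L
    d_imp[wh] <- major_hom[wh]
    # wrong hom -> het (80%) or opposite hom (20%)
    wo <- which(wrong & d_true != 1L & !is.na(d_true))
    to_het <- stats::runif(length(wo)) < 0.8
    d_imp[wo[to_het]] <- 1L
    d_imp[wo[!to_het]] <- 2L - d_true[wo[!to_het]]

    correct <- !wrong
    g <- numeric(n)
    g[correct] <- stats::rbeta(sum(correct), model$gp_correct[1],
                               model$gp_correct[2])
    g[!correct] <- stats::rbeta(sum(!correct), model$gp_wrong[1],
                                model$gp_wrong[2])
    g <- 0.5 + g / 2  # argmax of the GP triple is always the emitted call
    # runner-up class: truth class when the call is wrong; otherwise the
    # most-confusable class (het for a hom call, major hom for a het call)
    d_fill <- d_imp
    d_fill[is.na(d_fill)] <- 0L  # placeholder; rows re-masked to NA below
    runner <- ifelse(wrong, d_true,
                     ifelse(d_fill == 1L, major_hom, 1L))
    runner[is.na(runner)] <- 1L
    gp <- matrix(0, n, 3)
    rest <- 1 - g
    gp[cbind(seq_len(n), d_fill + 1L)] <- g
    gp[cbind(seq_len(n), runner + 1L)] <- gp[cbind(seq_len(n), runner + 1L)] +
      0.9 * rest
    third <- 3L - d_fill - runner  # the remaining class index (0+1+2 = 3)
    gp[cbind(seq_len(n), third + 1L)] <- gp[cbind(seq_len(n), third + 1L)] +
      0.1 * rest
    if (model$miss_rate > 0) {
      drop <- stats::runif(n) < model$miss_rate
      d_imp[drop] <- NA_integer_
      gp[drop, ] <- NA_real_
    }
    miss <- is.na(d_true)
    d_imp[miss] <- NA_integer_
    gp[miss, ] <- NA_real_
    new_callset(truth$sample_id, sites, d_imp, gp)
  })
}

#' Pseudohaploidize a truth callset by Poisson read sampling
#'
#' Emulates the random-allele calling used for low-coverage ancient genomes:
#' per-site read depth is Poisson(coverage); zero depth yields a missing
#' call, otherwise a single allele is sampled uniformly from the diploid
#' genotype (a heterozygote gives ref or alt with probability 1/2) and
#' recorded as the corresponding homozygous dosage. Expected missingness is
#' `exp(-coverage)`.
#'
#' @param truth truth [new_callset()].
#' @param coverage mean read depth (x-fold), > 0.
#' @param seed integer seed.
#' @return A pseudohaploid callset (dosages 0/2/NA, no GP).
#' @export
pseudohaploidize <- function(truth, coverage, seed = 1L) {
  stopifnot(coverage > 0)
  n <- length(truth$dosage)
  with_seed(seed, {
    depth <- stats::rpois(n, coverage)
    d <- truth$dosage
    out <- ifelse(d == 1L, ifelse(stats::runif(n) < 0.5, 0L, 2L), d)
    out[depth == 0 | is.na(d)] <- NA_integer_
    new_callset(truth$sample_id, truth$sites, out)
  })
}
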