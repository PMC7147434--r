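#' Build detection histories for the occupancy model
#'
#' Treats the PCR replicates of each water bottle as independent trials: for
#' every (ASV, bottle) pair, `y` is the number of replicates in which the ASV
#' was detected (count >= `detectThreshold`) and `K` the number of surviving
#' replicates of that bottle. Bottles where an ASV was never detected are
#' retained as `y = 0` histories — they inform the commonness `psi` and the
#' false-positive rate `p10`.
#'
#' @param x an [EdnaExperiment-class] (environmental samples are used).
#' @param detectThreshold minimum reads counting as a detection (default 1).
#' @return data.frame with columns `asv_id`, `bottle_id`, `y`, `K`.
#' @export
buildDetectionHistories <- function(x, detectThreshold = 1) {
  if (detectThreshold < 1) stop("detectThreshold must be >= 1")
  env <- environmentalSamples(x)
  if (ncol(env) == 0) stop("no environmental replicates")
  bt <- bottleId(env)
  det <- counts(env) >= detectThreshold
  y <- t(rowsum(t(det) + 0, bt))           # ASV x bottle detections
  K <- as.integer(table(bt)[colnames(y)])
  data.frame(asv_id = rep(rownames(y), times = ncol(y)),
             bottle_id = rep(colnames(y), each = nrow(y)),
             y = as.integer(y), K = rep(K, each = nrow(y)),
             stringsAsFactors = FALSE)
}

# Marginal log-likelihood of one ASV's histories: per bottle, the latent
# presence z is summed out of psi^z (1-psi)^(1-z) Binom(y | K, z p11 + (1-z) p10).
# Patterns (y, K) are collapsed with weights w for speed.
.occLoglik <- function(psi, p11, p10, yu, Ku, w, chooseKy) {
  f11 <- chooseKy * p11^yu * (1 - p11)^(Ku - yu)
  f10 <- chooseKy * p10^yu * (1 - p10)^(Ku - yu)
  sum(w * log(psi * f11 + (1 - psi) * f10))
}

.splitRhat <- function(chains) {
  # chains: list of numeric vectors (one per chain); split each in half
  halves <- unlist(lapply(chains, function(ch) {
    n <- floor(length(ch) / 2)
    list(ch[seq_len(n)], ch[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Bayesian occupancy model for one ASV
#'
#' Samples the posterior of (psi, p11, p10) — commonness, true-positive
#' detection rate and false-positive rate — under independent uniform(0,1)
#' priors truncated to `p10 < p11` (the standard identifiability constraint
#' for false-positive occupancy models), with the latent per-bottle presence
#' marginalized out of the binomial likelihood. Sampling is componentwise
#' random-walk Metropolis on the unit cube; split-R-hat over split half-chains
#' is reported and `converged` is `TRUE` when all values are below 1.05.
#'
#' @param y integer detections per bottle.
#' @param K integer trials (replicates) per bottle, recycled to `length(y)`.
#' @param asv optional ASV id label.
#' @param draws post-burn-in draws per chain (default 5000).
#' @param burnIn discarded initial draws per chain (default 2000).
#' @param chains number of chains (default 2).
#' @param seed RNG seed.
#' @param proposalSd random-walk step SD on the probability scale.
#' @return an [OccupancyPosterior-class].
#' @examples
#' fit <- fitOccupancyModel(y = c(3, 2, 0, 3), K = 3, draws = 500,
#'                          burnIn = 200, seed = 1)
#' fit@summary
#' @export
fitOccupancyModel <- function(y, K, asv = NA_character_, draws = 5000,
                              burnIn = 2000, chains = 2, seed = 1,
                              proposalSd = 0.15) {
  if (!length(y)) stop("need at least one detection history")
  K <- rep_len(K, length(y))
  if (any(y < 0 | y > K)) stop("histories must satisfy 0 <= y <= K")
  key <- paste(y, K)
  w <- as.numeric(table(key))
  uk <- do.call(rbind, strsplit(names(table(key)), " "))
  yu <- as.numeric(uk[, 1]); Ku <- as.numeric(uk[, 2])
  chooseKy <- choose(Ku, yu)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    th <- c(psi = runif(1, 0.2, 0.8), p11 = runif(1, 0.55, 0.95),
            p10 = runif(1, 0.02, 0.45))
    ll <- .occLoglik(th[1], th[2], th[3], yu, Ku, w, chooseKy)
    out <- matrix(NA_real_, burnIn + draws, 3,
                  dimnames = list(NULL, c("psi", "p11", "p10")))
    sds <- rep(proposalSd, 3)
    acc <- integer(3); tries <- integer(3)
    for (i in seq_len(burnIn + draws)) {
      for (j in 1:3) {
        prop <- th
        prop[j] <- th[j] + rnorm(1, 0, sds[j])
        tries[j] <- tries[j] + 1L
        ok <- prop[j] > 0 && prop[j] < 1 && prop[3] < prop[2]
        if (ok) {
          llp <- .occLoglik(prop[1], prop[2], prop[3], yu, Ku, w, chooseKy)
          if (log(runif(1)) < llp - ll) {
            th <- prop; ll <- llp; acc[j] <- acc[j] + 1L
          }
        }
      }
      # adapt proposal scales toward ~40% acceptance during burn-in only,
      # so the sampling phase remains a valid fixed-kernel chain
      if (i <= burnIn && i %% 100 == 0) {
        rate <- acc / pmax(tries, 1L)
        sds <- pmin(pmax(sds * exp(0.6 * (rate - 0.4)), 0.02), 1)
        acc[] <- 0L; tries[] <- 0L
      }
      out[i, ] <- th
    }
    out[-seq_len(burnIn), , drop = FALSE]
  }
  chain_draws <- lapply(seq_len(chains), function(c)
    run_chain(seed * 7919L + c))
  all <- do.call(rbind, chain_draws)
  rhat <- vapply(1:3, function(j)
    .splitRhat(lapply(chain_draws, function(d) d[, j])), 0)
  names(rhat) <- colnames(all)
  smry <- data.frame(
    parameter = colnames(all),
    mean = colMeans(all),
    lower = apply(all, 2, quantile, 0.025),
    upper = apply(all, 2, quantile, 0.975),
    rhat = rhat, row.names = NULL)
  new("OccupancyPosterior", asv = asv, draws = all, summary = smry,
      nChains = as.integer(chains), converged = all(rhat < 1.05))
}

#' Conditional presence probability given a detection history
#'
#' Closed-form probability that a taxon is truly present in a bottle given
#' `y` detections in `K` trials and fixed model parameters:
#' `psi p11^y (1-p11)^(K-y) / [psi p11^y (1-p11)^(K-y) +
#' (1-psi) p10^y (1-p10)^(K-y)]`.
#'
#' @param psi,p11,p10 occupancy, detection, false-positive probabilities.
#' @param y,K detections and trials (vectorized).
#' @return numeric probabilities in `[0, 1]`.
#' @examples
#' presenceProb(0.5, 0.8, 0.1, y = 0, K = 3)  # ~ 0.0109
#' @export
presenceProb <- function(psi, p11, p10, y, K) {
  a <- psi * p11^y * (1 - p11)^(K - y)
  b <- (1 - psi) * p10^y * (1 - p10)^(K - y)
  out <- a / (a + b)
  deg <- a + b == 0  # both likelihoods vanish (boundary parameters): prior
  if (any(deg)) out[deg] <- rep_len(psi, length(out))[deg]
  out
}

#' Posterior presence probability per detection history
#'
#' Averages the closed-form conditional presence probability over posterior
#' draws of (psi, p11, p10), for each supplied history; the ASV-level
#' "overall likelihood of occupancy" is the aggregate over that ASV's
#' bottles (`max` by default, `mean` optionally).
#'
#' @param fit an [OccupancyPosterior-class].
#' @param y,K detection histories (vectors, `K` recycled).
#' @param aggregate `"max"` (default) or `"mean"` over histories.
#' @return list: `perBottle` numeric per history, `overall` scalar.
#' @export
presenceProbability <- function(fit, y, K, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  K <- rep_len(K, length(y))
  d <- fit@draws
  per <- vapply(seq_along(y), function(i)
    mean(presenceProb(d[, "psi"], d[, "p11"], d[, "p10"], y[i], K[i])), 0)
  list(perBottle = per,
       overall = if (aggregate == "max") max(per) else mean(per))
}

#' Fit the occupancy model to every ASV
#'
#' Per-ASV independent fits of [fitOccupancyModel()] over the detection
#' histories from [buildDetectionHistories()]. ASVs sharing an identical
#' multiset of (y, K) histories have identical posteriors, so by default one
#' fit per unique pattern is computed and reused (`collapsePatterns`).
#' Non-converged fits are flagged, not fatal; such ASVs are retained
#' conservatively by [cullAsvs()].
#'
#' @param x an [EdnaExperiment-class].
#' @param detectThreshold passed to [buildDetectionHistories()].
#' @param draws,burnIn,chains,seed MCMC settings (see [fitOccupancyModel()]).
#' @param aggregate how per-bottle presence probabilities are combined.
#' @param collapsePatterns reuse fits across ASVs with identical histories.
#' @return data.frame, one row per ASV: posterior means and 95% credible
#'   bounds for psi/p11/p10, max split-R-hat, `converged`, and
#'   `presence_prob`.
#' @export
fitOccupancyAll <- function(x, detectThreshold = 1, draws = 5000,
                            burnIn = 2000, chains = 2, seed = 1,
                            aggregate = c("max", "mean"),
                            collapsePatterns = TRUE) {
  aggregate <- match.arg(aggregate)
  hist <- buildDetectionHistories(x, detectThreshold)
  asvs <- rownames(x)
  pat_of <- vapply(asvs, function(a) {
    h <- hist[hist$asv_id == a, ]
    paste(sort(paste(h$y, h$K)), collapse = ";")
  }, "")
  fit_one <- function(a) {
    h <- hist[hist$asv_id == a, ]
    fit <- fitOccupancyModel(h$y, h$K, asv = a, draws = draws,
                             burnIn = burnIn, chains = chains, seed = seed)
    pp <- presenceProbability(fit, h$y, h$K, aggregate)
    s <- fit@summary
    data.frame(asv_id = a,
               psi = s$mean[1], psi_lo = s$lower[1], psi_hi = s$upper[1],
               p11 = s$mean[2], p11_lo = s$lower[2], p11_hi = s$upper[2],
               p10 = s$mean[3], p10_lo = s$lower[3], p10_hi = s$upper[3],
               rhat_max = max(s$rhat), converged = fit@converged,
               presence_prob = pp$overall, stringsAsFactors = FALSE)
  }
  if (collapsePatterns) {
    reps <- asvs[!duplicated(pat_of)]
    fits <- do.call(rbind, lapply(reps, fit_one))
    out <- fits[match(pat_of, pat_of[match(reps, asvs)]), ]
    out$asv_id <- asvs
    rownames(out) <- asvs
  } else {
    out <- do.call(rbind, lapply(asvs, fit_one))
    rownames(out) <- asvs
  }
  out
}

#' Cull ASVs unlikely to be truly present
#'
#' Removes all records of ASVs whose overall presence probability is strictly
#' below `threshold` (default 0.2, i.e. the "< 20%" rule). Non-converged fits
#' are never culled.
#'
#' @param x an [EdnaExperiment-class].
#' @param posteriors data.frame from [fitOccupancyAll()], or a named numeric
#'   vector of presence probabilities.
#' @param threshold cull probability in `[0, 1]`.
#' @return filtered `EdnaExperiment` (provenance gains `"occupancy-filtered"`;
#'   `metadata()$occupancy_culled` lists removals).
#' @export
cullAsvs <- function(x, posteriors, threshold = 0.2) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  if (is.data.frame(posteriors)) {
    probs <- setNames(posteriors$presence_prob, posteriors$asv_id)
    keepAnyway <- setNames(!posteriors$converged, posteriors$asv_id)
  } else {
    probs <- posteriors
    keepAnyway <- setNames(rep(FALSE, length(probs)), names(probs))
  }
  probs <- probs[rownames(x)]
  keepAnyway <- keepAnyway[rownames(x)]
  keep <- is.na(probs) | probs >= threshold | keepAnyway
  message("occupancy cull: ", sum(!keep), " of ", nrow(x),
          " ASVs removed at threshold ", threshold)
  removed <- rownames(x)[!keep]
  x <- x[keep, ]
  provenance(x) <- c(provenance(x), "occupancy-filtered")
  metadata(x)$occupancy_culled <- removed
  x
}
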