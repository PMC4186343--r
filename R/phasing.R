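# Haplotypes are represented internally as keys: allele strings joined
# with "|" in site-panel order.
hap_key <- function(m) apply(m, 1, paste, collapse = "|")
hap_unkey <- function(keys) {
  do.call(rbind, strsplit(keys, "|", fixed = TRUE))
}

# Ordered allele-pair candidates at one site for one genotype call.
site_pair_candidates <- function(a, b, dict) {
  if (!is.na(a) && !is.na(b)) {
    if (a == b) return(list(c(a, a)))
    return(list(c(a, b), c(b, a)))
  }
  if (!is.na(a)) {  # half call: a plus any dictionary allele
    out <- list()
    for (x in dict) {
      out[[length(out) + 1L]] <- c(a, x)
      if (x != a) out[[length(out) + 1L]] <- c(x, a)
    }
    return(out)
  }
  out <- list()
  for (x in dict) for (y in dict) out[[length(out) + 1L]] <- c(x, y)
  out
}

# Enumerate the unordered haplotype pairs consistent with one sample's
# genotypes over a set of site indices.  Returns a 2-column matrix of hap
# keys (column 1 <= column 2) or NULL if the expansion exceeds `cap`.
enumerate_pairs <- function(gm, i, idx, cap = 4096L) {
  h1 <- ""
  h2 <- ""
  first <- TRUE
  for (j in idx) {
    cands <- site_pair_candidates(gm$allele_a[i, j], gm$allele_b[i, j],
                                  gm$sites$alleles[[j]])
    n_old <- length(h1)
    n_new <- n_old * length(cands)
    if (n_new > cap) return(NULL)
    sep <- if (first) "" else "|"
    nh1 <- character(n_new)
    nh2 <- character(n_new)
    k <- 0L
    for (cc in cands) {
      nh1[(k + 1L):(k + n_old)] <- paste0(h1, sep, cc[1])
      nh2[(k + 1L):(k + n_old)] <- paste0(h2, sep, cc[2])
      k <- k + n_old
    }
    # drop duplicated ordered states produced by half/missing expansion
    keep <- !duplicated(paste(nh1, nh2, sep = "/"))
    h1 <- nh1[keep]
    h2 <- nh2[keep]
    first <- FALSE
  }
  lo <- pmin(h1, h2)
  hi <- pmax(h1, h2)
  keep <- !duplicated(paste(lo, hi, sep = "/"))
  cbind(lo[keep], hi[keep])
}

# EM for haplotype frequencies given per-sample consistent pair lists.
# `pairs` is a list of 2-column key matrices.  Returns frequencies over
# the union of referenced haplotypes; the log-likelihood is monotone
# non-decreasing across iterations (recorded in `ll_trace`).
em_core <- function(pairs, init = NULL, tol = 1e-8, max_iter = 500L) {
  keys <- sort(unique(unlist(pairs)))
  nh <- length(keys)
  idx <- lapply(pairs, function(pm)
    cbind(match(pm[, 1], keys), match(pm[, 2], keys)))
  f <- if (is.null(init)) rep(1 / nh, nh) else init / sum(init)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    acc <- numeric(nh)
    ll <- 0
    for (s in seq_along(idx)) {
      pm <- idx[[s]]
      w <- f[pm[, 1]] * f[pm[, 2]] * ifelse(pm[, 1] == pm[, 2], 1, 2)
      tw <- sum(w)
      if (tw <= 0) next
      ll <- ll + log(tw)
      w <- w / tw
      for (r in seq_len(nrow(pm))) {
        acc[pm[r, 1]] <- acc[pm[r, 1]] + w[r]
        acc[pm[r, 2]] <- acc[pm[r, 2]] + w[r]
      }
    }
    f <- acc / sum(acc)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(freq = stats::setNames(f, keys), ll = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, converged = converged,
       final_delta = if (length(ll_trace) > 1)
         diff(utils::tail(ll_trace, 2)) else NA_real_)
}

#' EM haplotype frequency estimation on a window of sites
#'
#' Excoffier--Slatkin-style expectation--maximization over diplotype
#' expansions of unphased genotypes.  Missing and half-called alleles are
#' handled by summing over all completions consistent with the call.  The
#' log-likelihood is non-decreasing at every iteration; the run stops when
#' the improvement falls below `tol` or after `max_iter` iterations
#' (non-convergence is reported, not fatal).  Frequencies below
#' `prune_floor` are dropped and the rest renormalized.
#'
#' @param gm A genotype matrix (`hlag_gm`).
#' @param sites Integer indices of the window's sites (default: all;
#'   windows beyond ~12 sites may be refused via `cap`).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @param restarts Number of random restarts (first start is uniform);
#'   the best final likelihood is kept.
#' @param seed Seed for the restart draws.
#' @param prune_floor Frequency floor; default 1/(10 * 2N).
#' @param cap Per-sample expansion cap passed to the pair enumerator.
#' @return A list of class `hlag_pool`: `freq` (named, keys are
#'   `|`-joined allele vectors), `sites` (gene positions), `ll`,
#'   `ll_trace`, `converged`, and the per-sample `pairs` lists used.
#' @export
em_frequencies <- function(gm, sites = NULL, tol = 1e-8, max_iter = 500L,
                           restarts = 3L, seed = 1L, prune_floor = NULL,
                           cap = 4096L) {
  if (is.null(sites)) sites <- seq_len(nrow(gm$sites))
  ns <- nrow(gm$allele_a)
  pairs <- vector("list", ns)
  fallback <- logical(ns)
  for (i in seq_len(ns)) {
    pm <- enumerate_pairs(gm, i, sites, cap)
    if (is.null(pm)) {
      fallback[i] <- TRUE
      next
    }
    pairs[[i]] <- pm
  }
  used <- !fallback
  if (!any(used)) stop("no sample could be expanded within the cap")
  res <- em_multistart(pairs[used], restarts, seed, tol, max_iter)
  if (is.null(prune_floor)) prune_floor <- 1 / (10 * 2 * sum(used))
  fr <- prune_renorm(res$freq, prune_floor)
  structure(list(freq = fr, sites = gm$sites$gene_pos[sites],
                 ll = res$ll, ll_trace = res$ll_trace,
                 converged = res$converged, final_delta = res$final_delta,
                 pairs = pairs, fallback = fallback),
            class = "hlag_pool")
}

em_multistart <- function(pairs, restarts, seed, tol, max_iter) {
  keys <- sort(unique(unlist(pairs)))
  best <- NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) NULL else {
      x <- stats::rgamma(length(keys), 1)
      x / sum(x)
    }
    fit <- em_core(pairs, init, tol, max_iter)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  best
}

prune_renorm <- function(freq, floor) {
  fr <- freq[freq >= floor]
  if (!length(fr)) fr <- freq[which.max(freq)]
  fr / sum(fr)
}

#' Phase a genotype matrix by windowed EM with partition-ligation
#'
#' The site panel is split into contiguous windows small enough for exact
#' diplotype expansion; haplotype frequencies are estimated per window by
#' EM, then adjacent windows are ligated left-to-right: candidate
#' haplotypes of the merged block are concatenations of the retained
#' window haplotypes, each sample's consistent pairs are composed from its
#' window-level pairs, and EM is re-run on the merged block.  After the
#' final block each sample is assigned its most probable haplotype pair
#' (`argmax f(h1) f(h2)`, doubled for heterozygous pairs), the posterior
#' of that pair among the sample's consistent pairs is reported, and
#' missing alleles are imputed from the best pair.
#'
#' Samples whose expansion exceeds the cap, or that lose all candidate
#' pairs during retention, fall back to a maximum-likelihood completion
#' restricted to the final pool and are flagged.
#'
#' @param gm A genotype matrix.
#' @param window_size Sites per initial window (default 8).
#' @param top_k Haplotypes retained per block after each EM pass (by
#'   frequency; pairs needed to keep a sample consistent are always
#'   retained).
#' @param pair_cap Per-sample cap on composed pairs during ligation; the
#'   most probable pairs under the current block frequencies are kept.
#' @param tol,max_iter,restarts,seed EM controls, see [em_frequencies()].
#' @return An object of class `hlag_phased`: `pool` (final `hlag_pool`),
#'   `hap1`/`hap2` allele matrices, `posterior`, `imputed` logical matrix
#'   (slots filled from the best pair), `flagged` samples, and the input
#'   `genotypes`.
#' @export
partition_ligation_phase <- function(gm, window_size = 8L, top_k = 50L,
                                     pair_cap = 4096L, tol = 1e-8,
                                     max_iter = 500L, restarts = 3L,
                                     seed = 1L) {
  np <- nrow(gm$sites)
  ns <- nrow(gm$allele_a)
  windows <- split(seq_len(np), ceiling(seq_len(np) / window_size))

  # per-window expansion + EM
  blocks <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    idx <- windows[[w]]
    pairs <- vector("list", ns)
    fallback <- logical(ns)
    for (i in seq_len(ns)) {
      pm <- enumerate_pairs(gm, i, idx, pair_cap)
      if (is.null(pm)) fallback[i] <- TRUE else pairs[[i]] <- pm
    }
    fit <- em_multistart(pairs[!fallback], restarts, seed + w, tol,
                         max_iter)
    kept <- retain_haps(fit$freq, pairs, top_k)
    blocks[[w]] <- list(pairs = kept$pairs, freq = kept$freq,
                        fallback = fallback)
  }

  # ligate left to right
  cur <- blocks[[1]]
  for (w in seq_along(blocks)[-1]) {
    nxt <- blocks[[w]]
    pairs <- vector("list", ns)
    fallback <- cur$fallback | nxt$fallback
    for (i in seq_len(ns)) {
      if (fallback[i]) next
      pairs[[i]] <- compose_pairs(cur$pairs[[i]], nxt$pairs[[i]],
                                  cur$freq, nxt$freq, pair_cap)
    }
    fit <- em_multistart(pairs[!fallback], restarts, seed + 100L + w,
                         tol, max_iter)
    kept <- retain_haps(fit$freq, pairs, top_k)
    cur <- list(pairs = kept$pairs, freq = kept$freq,
                fallback = fallback, fit = fit)
  }
  if (length(blocks) == 1L)
    cur$fit <- em_multistart(cur$pairs[!cur$fallback], restarts,
                             seed + 101L, tol, max_iter)

  freq <- prune_renorm(cur$freq, 1 / (10 * 2 * ns))
  pool <- structure(list(freq = freq, sites = gm$sites$gene_pos,
                         ll = cur$fit$ll, ll_trace = cur$fit$ll_trace,
                         converged = cur$fit$converged),
                    class = "hlag_pool")

  # per-sample best pair
  hap1 <- matrix(NA_character_, ns, np, dimnames = dimnames(gm$allele_a))
  hap2 <- hap1
  posterior <- rep(NA_real_, ns)
  flagged <- logical(ns)
  pool_keys <- names(freq)
  for (i in seq_len(ns)) {
    pm <- cur$pairs[[i]]
    if (cur$fallback[i] || is.null(pm) || nrow(pm) == 0L) {
      # ML completion restricted to the final pool
      pm <- consistent_pool_pairs(gm, i, pool_keys)
      flagged[i] <- TRUE
      if (is.null(pm)) {
        # keep the unphased genotype; nothing consistent in the pool
        hap1[i, ] <- gm$allele_a[i, ]
        hap2[i, ] <- gm$allele_b[i, ]
        next
      }
    }
    w <- pair_weight(pm, freq)
    best <- which.max(w)
    posterior[i] <- w[best] / sum(w)
    hap1[i, ] <- strsplit(pm[best, 1], "|", fixed = TRUE)[[1]]
    hap2[i, ] <- strsplit(pm[best, 2], "|", fixed = TRUE)[[1]]
  }
  imputed <- is.na(gm$allele_a) | is.na(gm$allele_b)
  structure(list(pool = pool, hap1 = hap1, hap2 = hap2,
                 posterior = posterior, imputed = imputed,
                 flagged = flagged, genotypes = gm),
            class = "hlag_phased")
}

pair_weight <- function(pm, freq) {
  f1 <- freq[pm[, 1]]
  f2 <- freq[pm[, 2]]
  f1[is.na(f1)] <- 0
  f2[is.na(f2)] <- 0
  unname(f1 * f2 * ifelse(pm[, 1] == pm[, 2], 1, 2))
}

# keep the top_k haplotypes by frequency, plus whatever is needed so that
# every sample retains at least one consistent pair
retain_haps <- function(freq, pairs, top_k) {
  keep <- names(sort(freq, decreasing = TRUE))[
    seq_len(min(top_k, length(freq)))]
  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pm <- pairs[[i]]
    if (is.null(pm)) next
    ok <- pm[, 1] %in% keep & pm[, 2] %in% keep
    if (any(ok)) out[[i]] <- pm[ok, , drop = FALSE]
    else {
      w <- pair_weight(pm, freq)
      best <- pm[which.max(w), , drop = FALSE]
      keep <- union(keep, as.vector(best))
      out[[i]] <- best
    }
  }
  fr <- freq[names(freq) %in% keep]
  list(pairs = out, freq = fr / sum(fr))
}

# compose consistent pairs of a ligated block from two adjacent blocks
compose_pairs <- function(left, right, f_left, f_right, pair_cap) {
  n <- nrow(left) * nrow(right) * 2L
  h1 <- character(n)
  h2 <- character(n)
  w <- numeric(n)
  k <- 0L
  wl <- pair_weight(left, f_left)
  wr <- pair_weight(right, f_right)
  for (a in seq_len(nrow(left))) {
    for (b in seq_len(nrow(right))) {
      k <- k + 1L
      h1[k] <- paste0(left[a, 1], "|", right[b, 1])
      h2[k] <- paste0(left[a, 2], "|", right[b, 2])
      w[k] <- wl[a] * wr[b]
      k <- k + 1L
      h1[k] <- paste0(left[a, 1], "|", right[b, 2])
      h2[k] <- paste0(left[a, 2], "|", right[b, 1])
      w[k] <- wl[a] * wr[b]
    }
  }
  lo <- pmin(h1, h2)
  hi <- pmax(h1, h2)
  keep <- !duplicated(paste(lo, hi, sep = "/"))
  lo <- lo[keep]; hi <- hi[keep]; w <- w[keep]
  if (length(lo) > pair_cap) {
    ord <- order(-w)[seq_len(pair_cap)]
    lo <- lo[ord]; hi <- hi[ord]
  }
  cbind(lo, hi)
}

# all pool-restricted pairs consistent with sample i's genotypes
consistent_pool_pairs <- function(gm, i, pool_keys) {
  mats <- hap_unkey(pool_keys)
  ok_pairs <- NULL
  nh <- length(pool_keys)
  for (a in seq_len(nh)) {
    for (b in a:nh) {
      consistent <- TRUE
      for (j in seq_len(ncol(mats))) {
        ga <- gm$allele_a[i, j]
        gb <- gm$allele_b[i, j]
        pa <- mats[a, j]
        pb <- mats[b, j]
        if (!is.na(ga) && !is.na(gb)) {
          if (!((ga == pa && gb == pb) || (ga == pb && gb == pa))) {
            consistent <- FALSE
            break
          }
        } else if (!is.na(ga)) {
          if (ga != pa && ga != pb) {
            consistent <- FALSE
            break
          }
        }
      }
      if (consistent)
        ok_pairs <- rbind(ok_pairs, c(pool_keys[a], pool_keys[b]))
    }
  }
  ok_pairs
}

#' Summaries of phasing quality
#'
#' @param phased A result from [partition_ligation_phase()], or a numeric
#'   vector of best-pair posteriors.
#' @return A list: `mean_posterior`, `frac_above_0.9` and
#'   `n_haplotypes` (NA when only posteriors are given).
#' @export
phasing_summary <- function(phased) {
  if (is.numeric(phased)) {
    post <- phased
    nh <- NA_integer_
  } else {
    post <- phased$posterior
    nh <- length(phased$pool$freq)
  }
  if (!length(post)) stop("no assignments")
  post <- post[!is.na(post)]
  list(mean_posterior = mean(post),
       frac_above_0.9 = mean(post > 0.9),
       n_haplotypes = nh)
}

#' Project a haplotype pool onto a region's site list
#'
#' Haplotypes are restricted to the ordered subset of sites and
#' frequencies of identical projections are summed, e.g. extracting the
#' 3'UTR haplotypes from whole-gene extended haplotypes.
#'
#' @param pool An `hlag_pool` (from [em_frequencies()] or the `pool` of a
#'   phased result), or a named frequency vector with a `sites` attribute.
#' @param sites Gene positions to keep; must be a subset of the pool's.
#' @return An `hlag_pool` over the projected site list.
#' @export
extract_region <- function(pool, sites) {
  pool_sites <- if (inherits(pool, "hlag_pool")) pool$sites else
    attr(pool, "sites")
  freq <- if (inherits(pool, "hlag_pool")) pool$freq else pool
  idx <- match(sites, pool_sites)
  if (anyNA(idx))
    stop("unknown site(s) in projection: ",
         paste(sites[is.na(idx)], collapse = ", "))
  mats <- hap_unkey(names(freq))
  keys <- apply(mats[, idx, drop = FALSE], 1, paste, collapse = "|")
  agg <- tapply(freq, keys, sum)
  structure(list(freq = stats::setNames(as.numeric(agg), names(agg)),
                 sites = sites),
            class = "hlag_pool")
}
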