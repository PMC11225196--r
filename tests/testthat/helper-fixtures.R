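# shared fixtures: small cohorts and an independent minimal PLS/OPLS oracle

small_spec <- function(n = c(CN = 40, aMCI = 24, DEM = 12, SCD = 30), ...) {
  cohort_spec(n = n, ...)
}

make_cohort <- function(seed = 1, spec = small_spec(), atlas = default_atlas()) {
  co <- generate_cohort(spec, atlas, seed = seed)
  co$cn <- co$measures[co$measures$group == "CN", ]
  co$amci <- co$measures[co$measures$group == "aMCI", ]
  co$dem <- co$measures[co$measures$group == "DEM", ]
  co$scd <- co$measures[co$measures$group == "SCD", ]
  co
}

# independent one-component PLS1 oracle (direct NIPALS formulas, no reuse of
# package internals)
pls1_oracle <- function(x, y) {
  x <- as.matrix(x)
  yc <- y - mean(y)
  w <- drop(crossprod(x, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(x %*% w)
  b <- sum(t1 * yc) / sum(t1^2)
  list(w = w, t1 = t1, b = b, fitted = mean(y) + b * t1)
}

# independent single-y OPLS oracle used for leave-one-out loops
opls_oracle <- function(x, y, n_ortho = 1) {
  x <- as.matrix(x)
  yc <- y - mean(y)
  w <- drop(crossprod(x, yc)); w <- w / sqrt(sum(w^2))
  wo_list <- po_list <- list()
  for (i in seq_len(n_ortho)) {
    t1 <- drop(x %*% w)
    p <- drop(crossprod(x, t1)) / sum(t1^2)
    wo <- p - sum(w * p) * w
    wo <- wo / sqrt(sum(wo^2))
    to <- drop(x %*% wo)
    po <- drop(crossprod(x, to)) / sum(to^2)
    x <- x - tcrossprod(to, po)
    wo_list[[i]] <- wo; po_list[[i]] <- po
  }
  t1 <- drop(x %*% w)
  b <- sum(t1 * yc) / sum(t1^2)
  pred <- function(xn) {
    xn <- as.matrix(xn)
    for (i in seq_along(wo_list)) {
      xn <- xn - tcrossprod(drop(xn %*% wo_list[[i]]), po_list[[i]])
    }
    drop(mean(y) + b * (xn %*% w))
  }
  list(fitted = mean(y) + b * t1, predict = pred)
}

# brute-force Mann-Whitney AUC (concordant pairs + half ties)
mw_auc <- function(score, outcome) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# ECDF-sweep oracle for the maximum-separation location: maximal F_cn - F_dis
# over the real line (attained on intervals between pooled order statistics)
ks_separation_oracle <- function(cn, dis) {
  pts <- sort(unique(c(cn, dis)))
  d <- stats::ecdf(cn)(pts) - stats::ecdf(dis)(pts)
  list(max_sep = max(d), argmax_points = pts[d >= max(d) - 1e-12])
}

# all permutations of 1:n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}
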