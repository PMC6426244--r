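#' Transform right-skewed covariates toward normality
#'
#' Applies `log10(x + m/2)`, with `m` the smallest positive value of the
#' column, to covariates whose moment skewness exceeds 1; other columns pass
#' through unchanged. The transformation applied to each column is recorded
#' in the `"transforms"` attribute of the result so analyses can report it.
#'
#' @param data A data frame.
#' @param cols Character vector of columns to consider.
#' @return `data` with transformed columns and a `"transforms"` attribute
#'   (named character vector, `"log10_offset"` or `"identity"`).
#' @export
transform_covariates <- function(data, cols) {
  stopifnot(all(cols %in% names(data)))
  transforms <- stats::setNames(rep("identity", length(cols)), cols)
  for (cl in cols) {
    x <- data[[cl]]
    if (!is.numeric(x)) next
    if (moment_skewness(x) > 1 && any(x > 0)) {
      offset <- min(x[x > 0]) / 2
      data[[cl]] <- log10(x + offset)
      transforms[cl] <- "log10_offset"
    }
  }
  attr(data, "transforms") <- transforms
  data
}

moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(0)
  m <- mean(x)
  (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
}

#' Seasonal group comparison: Kruskal-Wallis with Dunn-Holm letters
#'
#' The omnibus Kruskal-Wallis rank test across groups, followed by pairwise
#' Dunn tests (large-sample z statistics on mean ranks with tie correction)
#' with Holm-adjusted p-values, summarised as a compact letter display at the
#' chosen significance level: groups sharing a letter are not significantly
#' different.
#'
#' @param values Numeric response (e.g. AO rates, nmol/L/day).
#' @param groups Group labels (e.g. season), same length as `values`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list of class `group_comparison` with elements `kruskal` (one-row
#'   tibble: `statistic`, `df`, `p_value`), `dunn` (tibble of pairwise
#'   comparisons: `z`, `p_raw`, `p_adj`), and `letters` (tibble of group,
#'   mean rank and letters).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(droplevels(groups)) < 2) rlang::abort("need at least 2 groups")
  if (any(table(groups) < 2)) rlang::abort("need at least 2 values per group")
  if (stats::sd(values) == 0) {
    rlang::abort("degenerate data: all values tied, ranks carry no information")
  }
  kw <- stats::kruskal.test(values, groups)
  dunn <- dunn_pairwise(values, groups)
  dunn$p_adj <- stats::p.adjust(dunn$p_raw, method = "holm")
  lv <- levels(droplevels(groups))
  sig_pairs <- dunn[dunn$p_adj < alpha, c("group1", "group2")]
  mean_ranks <- tapply(rank(values), droplevels(groups), mean)
  structure(
    list(
      kruskal = tibble::tibble(
        statistic = unname(kw$statistic),
        df = unname(kw$parameter),
        p_value = kw$p.value
      ),
      dunn = dunn,
      letters = tibble::tibble(
        group = lv,
        mean_rank = as.numeric(mean_ranks[lv]),
        letters = letter_display(lv, sig_pairs)
      ),
      alpha = alpha
    ),
    class = "group_comparison"
  )
}

# Dunn (1964) pairwise z on mean ranks, with tie correction.
dunn_pairwise <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  n_tot <- length(values)
  rk <- rank(values)
  mean_ranks <- tapply(rk, groups, mean)
  n_g <- table(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]
    g2 <- pairs[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
                 (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    tibble::tibble(
      group1 = g1, group2 = g2, z = z,
      p_raw = 2 * stats::pnorm(-abs(z))
    )
  }) |>
    purrr::list_rbind()
}

# Compact letter display by insert-and-absorb: start from one set holding all
# groups, split any set containing a significantly different pair, then drop
# sets contained in others.
letter_display <- function(groups, sig_pairs) {
  sets <- list(groups)
  if (nrow(sig_pairs) > 0) {
    for (k in seq_len(nrow(sig_pairs))) {
      g1 <- sig_pairs$group1[k]
      g2 <- sig_pairs$group2[k]
      new_sets <- list()
      for (s in sets) {
        if (g1 %in% s && g2 %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop sets that are subsets of another
      keep <- vapply(seq_along(new_sets), function(i) {
        !any(vapply(seq_along(new_sets), function(j) {
          i != j && all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[j]]) > length(new_sets[[i]]) || j < i)
        }, logical(1)))
      }, logical(1))
      sets <- new_sets[keep]
    }
  }
  vapply(groups, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  print(x$letters)
  invisible(x)
}

#' Paired t test on matched observations
#'
#' Classical paired t test on the differences `a - b` (e.g. top vs bottom
#' depth, paired by date). Identical vectors return `t = 0`, `p = 1`; a
#' constant nonzero difference (zero variance) is degenerate and raises an
#' error rather than claiming infinite evidence.
#'
#' @param a,b Numeric vectors of equal length >= 3, paired by position.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_test <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("paired vectors differ in length")
  if (length(a) < 3) rlang::abort("need at least 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(t = 0, df = length(d) - 1, p_value = 1,
                            mean_diff = 0))
    }
    rlang::abort("degenerate pairing: constant nonzero difference")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_diff = unname(tt$estimate)
  )
}

#' Pearson correlation between two series
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
correlate <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("vectors differ in length")
  if (length(a) < 3) rlang::abort("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rlang::abort("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}

#' Forward-selection multiple linear regression
#'
#' Greedy forward selection for a least-squares multiple regression of a
#' response on environmental covariates. Starting from the intercept-only
#' model, at each step the candidate with the smallest partial-F p-value is
#' added if that p-value is below `entry_alpha`; selection stops when no
#' candidate qualifies. Covariates are standardised (zero mean, unit SD)
#' internally so coefficients are comparable; optionally they are first
#' transformed toward normality (see [transform_covariates()]).
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param covariates Character vector of candidate covariate columns.
#' @param entry_alpha Partial-F entry threshold (default 0.05).
#' @param transform Transform skewed covariates first (default `TRUE`).
#' @return An object of class `ao_mlr`: list with `selected` (character, in
#'   entry order), `model` (the final `lm`), `r2`, `steps` (tibble of entry
#'   p-values), `transforms`, `n`.
#' @export
forward_mlr <- function(data, response, covariates, entry_alpha = 0.05,
                        transform = TRUE) {
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  if (nrow(data) < 8) rlang::abort("need at least 8 samples")
  dat <- data[, c(response, covariates)]
  dat <- dat[stats::complete.cases(dat), ]
  transforms <- stats::setNames(rep("identity", length(covariates)), covariates)
  if (transform) {
    dat <- transform_covariates(dat, covariates)
    transforms <- attr(dat, "transforms")
  }
  for (cl in covariates) {
    if (stats::sd(dat[[cl]]) == 0) {
      rlang::abort(paste0("covariate '", cl, "' is constant"))
    }
    dat[[cl]] <- as.numeric(scale(dat[[cl]]))
  }

  selected <- character(0)
  remaining <- covariates
  fit <- stats::lm(stats::reformulate("1", response), data = dat)
  steps <- list()
  while (length(remaining) > 0) {
    scope <- stats::reformulate(c(selected, remaining), response)
    tab <- stats::add1(fit, scope = scope, test = "F")
    cand <- tab[remaining, , drop = FALSE]
    pvals <- cand[["Pr(>F)"]]
    if (all(is.na(pvals))) {
      rlang::warn("remaining candidates are collinear with the model; stopping")
      break
    }
    best <- which.min(pvals)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(selected) + 1,
      variable = remaining[best],
      partial_f_p = pvals[best],
      entered = !is.na(pvals[best]) && pvals[best] < entry_alpha
    )
    if (is.na(pvals[best]) || pvals[best] >= entry_alpha) break
    selected <- c(selected, remaining[best])
    remaining <- setdiff(remaining, selected)
    fit <- stats::lm(stats::reformulate(selected, response), data = dat)
  }
  r2 <- if (length(selected) == 0) 0 else summary(fit)$r.squared
  structure(
    list(
      selected = selected,
      model = fit,
      r2 = r2,
      steps = purrr::list_rbind(steps),
      transforms = transforms,
      response = response,
      n = nrow(dat),
      entry_alpha = entry_alpha,
      data = dat
    ),
    class = "ao_mlr"
  )
}

#' @export
print.ao_mlr <- function(x, ...) {
  cat("<ao_mlr> forward-selection linear model\n")
  if (length(x$selected) == 0) {
    cat("  no covariate entered the model\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = " + "), "\n")
    cat(sprintf("  R-squared = %.3f on n = %d\n", x$r2, x$n))
  }
  invisible(x)
}

#' @rdname forward_mlr
#' @param x An `ao_mlr` object.
#' @param ... Unused.
#' @method tidy ao_mlr
#' @export
tidy.ao_mlr <- function(x, ...) {
  if (length(x$selected) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std_error = numeric(), p_value = numeric()))
  }
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    p_value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname forward_mlr
#' @method glance ao_mlr
#' @export
glance.ao_mlr <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r2,
    n = x$n,
    n_selected = length(x$selected),
    first_selected = if (length(x$selected) > 0) x$selected[1] else NA_character_
  )
}

#' Univariate regression tree with cross-validation pruning
#'
#' Binary recursive partitioning of a single response on numeric and factor
#' covariates (CART with the anova splitting rule): numeric splits fall at
#' midpoints between sorted unique values, factor splits search level subsets,
#' and the full tree is cost-complexity pruned to the size with the lowest
#' seeded k-fold cross-validation error (global minimum, not the 1-SE rule).
#' Minimum leaf size is 3. A constant response yields a single leaf.
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate columns (factors allowed,
#'   <= 8 levels each).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param min_leaf Minimum observations per leaf (default 3).
#' @return An object of class `ao_urt`: list with `tree` (pruned `rpart`),
#'   `splits` (tibble: node, variable, numeric `threshold` or factor
#'   `left_levels`), `leaf_means` (tibble), `r2`, `cv` (tibble of the
#'   complexity sequence with cross-validation error), `n`.
#' @export
fit_urt <- function(data, response, covariates, cv_folds = 10, seed = 1L,
                    min_leaf = 3) {
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  dat <- data[, c(response, covariates)]
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 10) rlang::abort("need at least 10 samples")
  for (cl in covariates) {
    if (is.character(dat[[cl]]) || is.logical(dat[[cl]])) {
      dat[[cl]] <- as.factor(dat[[cl]])
    }
    if (is.factor(dat[[cl]]) && nlevels(dat[[cl]]) > 8) {
      rlang::abort(paste0("factor '", cl, "' has more than 8 levels"))
    }
  }
  form <- stats::reformulate(covariates, response)
  full <- withr::with_seed(seed, {
    rpart::rpart(
      form, data = dat, method = "anova",
      control = rpart::rpart.control(
        xval = cv_folds, minbucket = min_leaf, minsplit = 2 * min_leaf,
        cp = 1e-4
      )
    )
  })
  cpt <- as.data.frame(full$cptable)
  # most parsimonious tree at the global cross-validation minimum
  if ("xerror" %in% names(cpt) && nrow(cpt) > 1) {
    best <- which.min(cpt$xerror)
    pruned <- rpart::prune(full, cp = cpt$CP[best])
  } else {
    pruned <- full
  }
  y <- dat[[response]]
  pred <- stats::predict(pruned, dat)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - pred)^2) / sst

  frame <- pruned$frame
  leaves <- frame$var == "<leaf>"
  structure(
    list(
      tree = pruned,
      splits = extract_rpart_splits(pruned),
      leaf_means = tibble::tibble(
        node = as.integer(rownames(frame)[leaves]),
        mean = frame$yval[leaves],
        n = frame$n[leaves]
      ),
      r2 = r2,
      cv = tibble::tibble(
        cp = cpt$CP,
        n_splits = cpt$nsplit,
        rel_error = cpt$`rel error`,
        cv_error = if ("xerror" %in% names(cpt)) cpt$xerror else NA_real_,
        cv_se = if ("xstd" %in% names(cpt)) cpt$xstd else NA_real_
      ),
      response = response,
      n = nrow(dat)
    ),
    class = "ao_urt"
  )
}

# Primary split per internal node of an rpart tree, in frame order.
extract_rpart_splits <- function(fit) {
  frame <- fit$frame
  internal <- which(frame$var != "<leaf>")
  if (length(internal) == 0) {
    return(tibble::tibble(node = integer(), variable = character(),
                          threshold = numeric(), left_levels = character()))
  }
  splits <- fit$splits
  xlev <- attr(fit, "xlevels")
  idx <- 1
  out <- vector("list", length(internal))
  for (k in seq_along(internal)) {
    i <- internal[k]
    row <- splits[idx, ]
    var <- as.character(frame$var[i])
    if (row[["ncat"]] > 1) {
      cs <- fit$csplit[row[["index"]], seq_len(row[["ncat"]])]
      lev <- xlev[[var]]
      out[[k]] <- tibble::tibble(
        node = as.integer(rownames(frame)[i]), variable = var,
        threshold = NA_real_,
        left_levels = paste(lev[cs == 1], collapse = ",")
      )
    } else {
      out[[k]] <- tibble::tibble(
        node = as.integer(rownames(frame)[i]), variable = var,
        threshold = unname(row[["index"]]), left_levels = NA_character_
      )
    }
    idx <- idx + 1 + frame$ncompete[i] + frame$nsurrogate[i]
  }
  purrr::list_rbind(out)
}

#' @export
print.ao_urt <- function(x, ...) {
  cat("<ao_urt> univariate regression tree\n")
  if (nrow(x$splits) == 0) {
    cat("  single leaf (no split)\n")
  } else {
    cat(sprintf("  %d split(s), %d leaves, R-squared = %.3f on n = %d\n",
                nrow(x$splits), nrow(x$leaf_means), x$r2, x$n))
    root <- x$splits[1, ]
    if (!is.na(root$threshold)) {
      cat(sprintf("  root: %s < %.4g\n", root$variable, root$threshold))
    } else {
      cat(sprintf("  root: %s in {%s}\n", root$variable, root$left_levels))
    }
  }
  invisible(x)
}

#' @rdname fit_urt
#' @param x An `ao_urt` object.
#' @param ... Unused.
#' @method tidy ao_urt
#' @export
tidy.ao_urt <- function(x, ...) x$splits

#' @rdname fit_urt
#' @method glance ao_urt
#' @export
glance.ao_urt <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r2,
    n = x$n,
    n_splits = nrow(x$splits),
    n_leaves = nrow(x$leaf_means),
    cv_error_min = suppressWarnings(min(x$cv$cv_error, na.rm = TRUE))
  )
}
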