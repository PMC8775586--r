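#' @include AllClasses.R
NULL

#' Significance stars
#'
#' "***" for p < 0.001, "**" for p < 0.01, "*" for p < 0.05 (strict
#' inequalities), else "".
#'
#' @param p p-value in [0, 1].
#' @return character.
#' @export
pStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

testResult <- function(parameter, category, test, n, statistic, p, flag = "") {
  data.frame(parameter = parameter, category = category, test = test,
             n = n, statistic = statistic, p_value = p, stars = pStars(p),
             flag = flag, stringsAsFactors = FALSE)
}

#' Paired sign test between channels
#'
#' Two-sided exact binomial test on the signs of per-scene UV - green
#' differences; exact zeros are dropped (classical sign test) and counted.
#' Fewer than 5 non-zero pairs flags the result as underpowered.
#'
#' @param valuesUv,valuesGreen equal-length per-scene value vectors in the
#'   same scene order.
#' @param parameter,category labels carried into the result.
#' @return one-row data.frame: parameter, category, test, n, statistic
#'   (number of positive differences), p_value, stars, flag.
#' @export
pairedSignTest <- function(valuesUv, valuesGreen, parameter = "",
                           category = "") {
  if (length(valuesUv) != length(valuesGreen))
    stop("paired vectors must have equal length")
  d <- valuesUv - valuesGreen
  d <- d[!is.na(d)]
  nTies <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  k <- sum(d > 0)
  flag <- if (n < 5) "underpowered" else ""
  if (nTies > 0) flag <- paste0(flag, if (nzchar(flag)) ";", nTies, " ties dropped")
  p <- if (n == 0) 1 else stats::binom.test(k, n, p = 0.5)$p.value
  testResult(parameter, category, "sign", n, k, p, flag)
}

#' Wilcoxon rank-sum (Mann-Whitney) test between groups
#'
#' Exact enumeration when both groups have at most 10 untied values,
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param groupA,groupB numeric vectors (each >= 2 values).
#' @param parameter,category labels carried into the result.
#' @return one-row data.frame as in \code{\link{pairedSignTest}} (statistic
#'   is the Mann-Whitney U of group A).
#' @export
ranksumTest <- function(groupA, groupB, parameter = "", category = "") {
  groupA <- groupA[!is.na(groupA)]
  groupB <- groupB[!is.na(groupB)]
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need at least 2 values")
  ties <- any(duplicated(c(groupA, groupB)))
  exact <- length(groupA) <= 10 && length(groupB) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, exact = exact, correct = TRUE))
  testResult(parameter, category, "ranksum",
             length(groupA) + length(groupB),
             unname(wt$statistic), min(wt$p.value, 1))
}

#' Long-format parameter table for channel comparisons
#'
#' Binds per-scene statistic rows (see \code{\link{computeSceneStats}}),
#' restricts to the "up" and "down" elevation categories (horizontal scenes
#' are excluded from hypothesis tests, as for the real image sets, but
#' remain available for intensity profiles), and checks that each
#' (scene, channel, parameter) appears exactly once.
#'
#' @param sceneStats list of per-scene data.frames or one bound data.frame
#'   with columns scene, category, channel, parameter, value.
#' @return data.frame restricted to categories up/down, with attribute
#'   \code{"nExcluded"} (horizontal scene count).
#' @export
buildParamTable <- function(sceneStats) {
  tab <- if (is.data.frame(sceneStats)) sceneStats else do.call(rbind, sceneStats)
  need <- c("scene", "category", "channel", "parameter", "value")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  bad <- unique(tab$scene[!tab$category %in% c("up", "down", "horizontal")])
  if (length(bad))
    stop("scenes with missing/unknown category: ", paste(bad, collapse = ", "))
  horiz <- unique(tab$scene[tab$category == "horizontal"])
  out <- tab[tab$category %in% c("up", "down"), , drop = FALSE]
  key <- paste(out$scene, out$channel, out$parameter)
  if (anyDuplicated(key))
    stop("duplicate (scene, channel, parameter) rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  attr(out, "nExcluded") <- length(horiz)
  out
}

#' Default comparison plan
#'
#' Sign tests on the per-sigma Weibull scale/shape, the per-direction
#' power-law slope/intercept and the representative autocorrelation values;
#' rank-sum tests comparing the left and right side fits of the chromatic
#' contrast distribution.
#'
#' @param sigmas LoG scales present in the table.
#' @return data.frame with columns parameter, test.
#' @export
defaultComparisonPlan <- function(sigmas = c(5, 10, 20, 40)) {
  signParams <- c(
    paste0("weibull_beta_s", sigmas), paste0("weibull_gamma_s", sigmas),
    "powerlaw_a_h", "powerlaw_a_v", "powerlaw_b_h", "powerlaw_b_v",
    "acf_50_0", "acf_0_50")
  ranksumParams <- c("chrom_beta", "chrom_gamma")
  data.frame(
    parameter = c(signParams, ranksumParams),
    test = c(rep("sign", length(signParams)),
             rep("ranksum", length(ranksumParams))),
    stringsAsFactors = FALSE)
}

#' Run the planned channel comparisons
#'
#' For sign tests, pairs UV and green values per scene within each category.
#' For rank-sum tests, compares the left-side and right-side values of the
#' chromatic contrast fits across scenes within each category.
#'
#' @param table a \code{\link{buildParamTable}} output.
#' @param plan data.frame with columns parameter, test (default
#'   \code{\link{defaultComparisonPlan}} for the sigmas present).
#' @return data.frame of test results (one row per parameter x category);
#'   parameters absent from the table are recorded in attribute
#'   \code{"skipped"}.
#' @export
runComparisons <- function(table, plan = NULL) {
  if (is.null(plan)) {
    sig <- sort(unique(as.numeric(sub(
      "^weibull_beta_s", "", grep("^weibull_beta_s", table$parameter, value = TRUE)))))
    plan <- defaultComparisonPlan(if (length(sig)) sig else c(5, 10, 20, 40))
  }
  if (nrow(plan) == 0)
    return(data.frame(parameter = character(), category = character(),
                      test = character(), n = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      stars = character(), flag = character()))
  out <- list(); skipped <- character()
  for (catg in intersect(c("up", "down"), unique(table$category))) {
    sub <- table[table$category == catg, , drop = FALSE]
    for (i in seq_len(nrow(plan))) {
      par <- plan$parameter[i]
      rows <- sub[sub$parameter == par, , drop = FALSE]
      if (nrow(rows) == 0) { skipped <- c(skipped, paste(par, catg)); next }
      if (plan$test[i] == "sign") {
        uv <- rows[rows$channel == "UV", ]
        gr <- rows[rows$channel == "Green", ]
        scn <- intersect(uv$scene, gr$scene)
        if (!length(scn)) { skipped <- c(skipped, paste(par, catg)); next }
        res <- pairedSignTest(uv$value[match(scn, uv$scene)],
                              gr$value[match(scn, gr$scene)], par, catg)
      } else {
        a <- rows$value[rows$channel == "left"]
        b <- rows$value[rows$channel == "right"]
        if (length(a) < 2 || length(b) < 2) {
          skipped <- c(skipped, paste(par, catg)); next
        }
        res <- ranksumTest(a, b, par, catg)
      }
      out[[length(out) + 1L]] <- res
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(parameter = character(), category = character(),
               test = character(), n = numeric(), statistic = numeric(),
               p_value = numeric(), stars = character(), flag = character())
  attr(res, "skipped") <- skipped
  res
}

#' Write a readable comparison report
#'
#' @param results a \code{\link{runComparisons}} data.frame.
#' @param path output markdown file.
#' @return invisibly, \code{path}.
#' @export
writeComparisonReport <- function(results, path) {
  lines <- c("# Channel comparison report", "")
  for (catg in unique(results$category)) {
    lines <- c(lines, sprintf("## %s visual field", catg), "")
    sub <- results[results$category == catg, ]
    lines <- c(lines,
      "| parameter | test | n | statistic | p | |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %s | %d | %.4g | %.3g | %s |",
              sub$parameter, sub$test, sub$n, sub$statistic,
              sub$p_value, sub$stars),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}
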