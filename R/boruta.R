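#' Shadow-feature (Boruta-style) all-relevant feature selection
#'
#' Each round appends a column-shuffled "shadow" copy of every candidate
#' feature, fits a random-forest importance model, and credits a feature
#' with a hit when its importance exceeds the best shadow importance.
#' Features are accepted or rejected by two-sided binomial tests on their
#' hit counts against the chance rate 1/2, Bonferroni-corrected over the
#' features still undecided; features still undecided when the round cap
#' is reached are rejected (conservative).
#'
#' @param table A [feature_table()] containing training rows only, or a
#'   plain feature matrix (then `labels` is required).
#' @param labels Training labels when `table` is a matrix.
#' @param n_trees Trees per importance forest.
#' @param alpha Test level for the binomial decisions.
#' @param max_rounds Round cap.
#' @param min_rounds Rounds before the first decision is allowed.
#' @param seed Seed controlling shuffles and forests.
#' @return Logical mask over the original features (TRUE = accepted) with
#'   attributes `hits`, `rounds` and `decision`
#'   (accepted/rejected/undecided).
#' @export
boruta_select <- function(table, labels = NULL, n_trees = 300,
                          alpha = 0.05, max_rounds = 100L,
                          min_rounds = 5L, seed = 1L) {
  if (inherits(table, "feature_table")) {
    x <- table$features
    y <- table$labels
  } else {
    x <- as.matrix(table)
    y <- factor(labels, levels = c("control", "case"))
  }
  if (nlevels(droplevels(y)) < 2) abort("labels are single-class")
  p <- ncol(x)
  feat_names <- colnames(x)
  decision <- rep("undecided", p)
  hits <- integer(p)
  tested <- integer(p)
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    active <- decision != "rejected"
    if (!any(decision == "undecided")) break
    rounds <- r
    rs <- derive_seed(seed, r)
    res <- with_seed(rs, {
      xa <- x[, active, drop = FALSE]
      shadow <- apply(xa, 2, sample)
      colnames(shadow) <- paste0("shadow_", colnames(xa))
      ranger::ranger(
        x = cbind(xa, shadow), y = y, num.trees = n_trees,
        importance = "impurity", num.threads = 1,
        seed = derive_seed(seed, r + 100000L)
      )$variable.importance
    })
    n_active <- sum(active)
    imp_real <- res[seq_len(n_active)]
    imp_shadow_max <- max(res[n_active + seq_len(n_active)])
    hit_now <- imp_real > imp_shadow_max
    hits[active] <- hits[active] + as.integer(hit_now)
    tested[active] <- tested[active] + 1L
    if (r >= min_rounds) {
      und <- which(decision == "undecided")
      m <- length(und)
      for (f in und) {
        p_hi <- stats::pbinom(hits[f] - 1L, tested[f], 0.5,
                              lower.tail = FALSE)
        p_lo <- stats::pbinom(hits[f], tested[f], 0.5)
        if (p_hi * m < alpha) decision[f] <- "accepted"
        else if (p_lo * m < alpha) decision[f] <- "rejected"
      }
    }
  }
  mask <- decision == "accepted"
  names(mask) <- feat_names
  attr(mask, "hits") <- hits
  attr(mask, "rounds") <- rounds
  attr(mask, "decision") <- decision
  mask
}
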