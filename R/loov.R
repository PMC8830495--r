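# Leave-one-out validation: train on N-1 members, predict the held-out one,
# repeat N times; summarise deviations from the known fractions.

fold_seed <- function(seed, i) {
  # deterministic per-fold seed, independent across folds, < 2^31
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483629)
}

#' Leave-one-out validation of a reference set
#'
#' For each member i, trains a map on the other N-1 members (with a seed
#' derived deterministically from `config$seed` and i, so folds are
#' independent yet reproducible), predicts member i, and tabulates the
#' deviations predicted - true per structure class.  Because both prediction
#' and truth sum to 1, the "other" deviation is always minus the sum of the
#' helix and sheet deviations.  Members named in `exclude` (for instance a
#' largely unfolded protein) still get a table row but are omitted from the
#' summary means.
#'
#' @param refset A [reference_set()] with at least 3 members.
#' @param config A [som_config()]; `n_steps` is used as given for every fold
#'   (folds are conventionally trained for fewer steps than full-set maps).
#' @param exclude Character vector of member labels excluded from the
#'   summary statistics.
#' @return Object of class `loov_result`: `table` (one row per member with
#'   true and predicted fractions, deviations and NRMSD), `summary` (mean
#'   absolute helix and sheet deviation over included members, mean NRMSD),
#'   `exclusions`, `config`.
#' @export
loov <- function(refset, config = som_config(), exclude = character()) {
  stopifnot(inherits(refset, "reference_set"))
  n <- length(refset$labels)
  if (n < 3) stop("leave-one-out validation needs at least 3 members",
                  call. = FALSE)
  bad <- setdiff(exclude, refset$labels)
  if (length(bad))
    stop(sprintf("exclude labels not in reference set: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- fold_seed(config$seed, i)
    train_i <- refset_drop(refset, i)
    map <- tryCatch(som_train(train_i, cfg_i),
                    error = function(e) stop(sprintf(
                      "fold '%s': %s", refset$labels[i], conditionMessage(e)),
                      call. = FALSE))
    pred <- predict(map, refset_member(refset, i))
    tr <- refset$fractions[i, ]
    pf <- pred$fractions
    rows[[i]] <- data.frame(
      label = refset$labels[i],
      true_helix = tr[["helix"]], true_sheet = tr[["sheet"]],
      true_other = tr[["other"]],
      pred_helix = pf[["helix"]], pred_sheet = pf[["sheet"]],
      pred_other = pf[["other"]],
      dev_helix = pf[["helix"]] - tr[["helix"]],
      dev_sheet = pf[["sheet"]] - tr[["sheet"]],
      dev_other = pf[["other"]] - tr[["other"]],
      nrmsd = pred$nrmsd)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  inc <- !(tab$label %in% exclude)
  structure(list(
    table = tab,
    summary = list(mean_abs_helix_dev = mean(abs(tab$dev_helix[inc])),
                   mean_abs_sheet_dev = mean(abs(tab$dev_sheet[inc])),
                   mean_nrmsd = mean(tab$nrmsd[inc]),
                   n_included = sum(inc)),
    exclusions = exclude,
    config = config), class = "loov_result")
}

#' @export
print.loov_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<loov_result: %d members (%d in summary)>\n", nrow(x$table), s$n_included))
  cat(sprintf("  mean |helix deviation| %.4f\n  mean |sheet deviation| %.4f\n",
              s$mean_abs_helix_dev, s$mean_abs_sheet_dev))
  cat(sprintf("  mean NRMSD %.4f\n", s$mean_nrmsd))
  invisible(x)
}

#' Ordered deviation table
#'
#' Returns the per-member table sorted by true helix content decreasing (the
#' conventional plotting order), with ties kept stable by label, and adds a
#' `nrmsd5` column (5 x NRMSD, the usual overlay scale on deviation plots).
#'
#' @param result A [loov()] result.
#' @param order Ordering rule; only `"helix_desc"` is defined.
#' @return data.frame.
#' @export
deviation_table <- function(result, order = "helix_desc") {
  stopifnot(inherits(result, "loov_result"))
  order <- match.arg(order, "helix_desc")
  tab <- result$table
  tab <- tab[base::order(-tab$true_helix, tab$label), ]
  tab$nrmsd5 <- 5 * tab$nrmsd
  rownames(tab) <- NULL
  tab
}
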