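#' Match detected candidates to ground-truth lesions
#'
#' Greedy one-to-one matching by ascending centroid distance: candidate and
#' truth pairs within \code{max_dist} mm are true positives, unmatched
#' truths are false negatives, unmatched candidates false positives. The
#' 5 mm default is half the largest target lesion diameter.
#'
#' @param candidates data.frame with columns z, y, x (mm) (as from
#'   [extract_candidates()]).
#' @param truths data.frame with columns z, y, x (mm).
#' @param max_dist matching radius (mm, > 0).
#' @return list(tp, fp, fn, matches) where matches is a data.frame of
#'   candidate index, truth index and distance.
#' @export
match_lesions <- function(candidates, truths, max_dist = 5) {
  if (max_dist <= 0) stop("max_dist must be > 0")
  nc <- nrow(candidates)
  nt <- nrow(truths)
  matches <- data.frame(candidate = integer(0), truth = integer(0),
                        dist = numeric(0))
  if (nc > 0 && nt > 0) {
    cm <- as.matrix(candidates[, c("z", "y", "x")])
    tm <- as.matrix(truths[, c("z", "y", "x")])
    dmat <- outer(seq_len(nc), seq_len(nt), Vectorize(function(i, j)
      sqrt(sum((cm[i, ] - tm[j, ])^2))))
    pairs <- which(dmat <= max_dist, arr.ind = TRUE)
    if (nrow(pairs)) {
      dists <- dmat[pairs]
      ord <- order(dists, pairs[, 1], pairs[, 2])
      used_c <- logical(nc)
      used_t <- logical(nt)
      for (r in ord) {
        i <- pairs[r, 1]
        j <- pairs[r, 2]
        if (used_c[i] || used_t[j]) next
        used_c[i] <- TRUE
        used_t[j] <- TRUE
        matches <- rbind(matches,
                         data.frame(candidate = i, truth = j,
                                    dist = dmat[i, j]))
      }
    }
  }
  tp <- nrow(matches)
  list(tp = tp, fp = nc - tp, fn = nt - tp, matches = matches)
}

#' Score a cohort of subjects
#'
#' Pools true/false positives and false negatives across subjects and
#' reports lesion-level (pooled) sensitivity TP / (TP + FN), the paper-style
#' arithmetic for counting missed lesions out of the cohort total.
#'
#' @param subjects named list; each element is
#'   \code{list(candidates = <data.frame>, truths = <data.frame>)}.
#' @param max_dist matching radius (mm).
#' @param json_path optional path for a machine-readable JSON report.
#' @return \code{ctavg_cohort_result}: per-subject counts, pooled counts,
#'   pooled sensitivity (3 decimals; NULL when there are no truths) and the
#'   per-lesion match table.
#' @export
evaluate_cohort <- function(subjects, max_dist = 5, json_path = NULL) {
  if (!length(subjects)) stop("need at least one subject")
  if (is.null(names(subjects)) || any(!nzchar(names(subjects))))
    names(subjects) <- sprintf("subject_%d", seq_along(subjects))
  per <- lapply(names(subjects), function(id) {
    s <- subjects[[id]]
    m <- match_lesions(s$candidates, s$truths, max_dist)
    list(subject = id, tp = m$tp, fp = m$fp, fn = m$fn,
         matches = m$matches)
  })
  tp <- sum(vapply(per, `[[`, integer(1), "tp"))
  fp <- sum(vapply(per, `[[`, integer(1), "fp"))
  fn <- sum(vapply(per, `[[`, integer(1), "fn"))
  sens <- if (tp + fn > 0) round(tp / (tp + fn), 3) else NULL
  res <- structure(list(
    per_subject = data.frame(
      subject = vapply(per, `[[`, character(1), "subject"),
      tp = vapply(per, `[[`, integer(1), "tp"),
      fp = vapply(per, `[[`, integer(1), "fp"),
      fn = vapply(per, `[[`, integer(1), "fn")),
    tp = tp, fp = fp, fn = fn,
    n_truth = tp + fn, sensitivity = sens,
    matches = lapply(per, `[[`, "matches")),
    class = "ctavg_cohort_result")
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_subject = res$per_subject, tp = tp, fp = fp, fn = fn,
           n_truth = tp + fn, sensitivity = sens),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

#' @export
print.ctavg_cohort_result <- function(x, ...) {
  cat("<ctavg_cohort_result>\n")
  print(x$per_subject, row.names = FALSE)
  cat(sprintf("pooled: TP %d  FP %d  FN %d  (%d truths)\n", x$tp, x$fp,
              x$fn, x$n_truth))
  if (!is.null(x$sensitivity))
    cat(sprintf("sensitivity: %.3f\n", x$sensitivity))
  else cat("sensitivity: undefined (no ground-truth lesions)\n")
  invisible(x)
}

#' Read a cohort ground-truth table
#'
#' Expects the tab-separated schema written by [generate_cohort()]:
#' subject, x, y, z (mm), diameter_mm, label; x/y/z are column/row/axial.
#'
#' @param path TSV file
#' @return data.frame with columns subject, z, y, x, diameter_mm, label
#' @export
read_truth <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "x", "y", "z")
  if (!all(need %in% names(tr)))
    stop("truth file must have columns ", paste(need, collapse = ", "))
  tr
}
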