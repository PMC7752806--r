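#' Blockwise conditioned-response percentages
#'
#' Aggregates per-trial CR calls into blocks of `block_size` consecutive
#' acquisition trials and returns the percentage of CR-present trials per
#' block. CS+ and CS- trials are pooled by default (both are scored over
#' identical windows by the detector); set `cs_plus_only = TRUE` for a
#' sensitivity analysis restricted to reinforced trials (block denominators
#' then vary with the pseudorandom ordering).
#'
#' @param results Per-trial detection results ([detect_session()] output), or
#'   a logical vector of CR calls in presentation order.
#' @param block_size Trials per block; 10 throughout this design (60 Week-1
#'   trials in 6 blocks, 30 Week-2 trials in 3 blocks).
#' @param cs_plus_only Score CS+ trials only.
#' @return Numeric vector of percentages in `[0, 100]`, one per block.
#' @export
block_cr_percent <- function(results, block_size = 10, cs_plus_only = FALSE) {
  if (is.data.frame(results)) {
    if (any(results$kind == "US_ALONE")) {
      stop("US-alone trials must be excluded before CR scoring")
    }
    cr <- results$cr_present
    kinds <- results$kind
  } else {
    cr <- as.logical(results)
    kinds <- rep("CS_PLUS", length(cr))
  }
  n <- length(cr)
  if (n == 0L || n %% block_size != 0L) {
    stop("trial count must be a positive multiple of block_size")
  }
  block <- rep(seq_len(n %/% block_size), each = block_size)
  if (cs_plus_only) {
    keep <- kinds == "CS_PLUS"
    tapply_pct <- vapply(split(cr[keep], block[keep]),
                         function(x) 100 * mean(x), numeric(1))
    as.numeric(tapply_pct)
  } else {
    as.numeric(vapply(split(cr, block), function(x) 100 * mean(x), numeric(1)))
  }
}

#' Assemble the cohort learning matrix
#'
#' Builds the subjects-by-blocks matrix fed to clustering and the ANCOVA:
#' each row is the concatenation of the 6 Week-1 block CR percentages and the
#' 3 Week-2 block CR percentages, columns `w1b1..w1b6, w2b1..w2b3` in that
#' fixed order. Subjects missing either session are excluded and listed in
#' the `excluded` attribute.
#'
#' @param results_by_subject Named list; for each subject id a list with
#'   `week1` and `week2` detection-result data frames (acquisition trials
#'   only or full sessions -- US-alone rows are dropped here).
#' @param block_size Trials per block.
#' @return Numeric matrix (subjects x 9) with subject-id rownames and an
#'   `excluded` character-vector attribute.
#' @export
assemble_learning_matrix <- function(results_by_subject, block_size = 10) {
  ids <- names(results_by_subject)
  rows <- list()
  excluded <- character(0)
  for (id in ids) {
    res <- results_by_subject[[id]]
    if (is.null(res$week1) || is.null(res$week2)) {
      excluded <- c(excluded, id)
      next
    }
    w1 <- res$week1[res$week1$phase == "acquisition", , drop = FALSE]
    w2 <- res$week2[res$week2$phase == "acquisition", , drop = FALSE]
    rows[[id]] <- c(block_cr_percent(w1, block_size),
                    block_cr_percent(w2, block_size))
  }
  if (length(rows) == 0L) {
    mat <- matrix(numeric(0), nrow = 0, ncol = 9)
  } else {
    mat <- do.call(rbind, rows)
  }
  colnames(mat) <- c(paste0("w1b", 1:6), paste0("w2b", 1:3))
  structure(mat, excluded = excluded)
}
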