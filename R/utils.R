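#' Derive a stage-specific sub-seed from a master seed
#'
#' Pipeline stages (splitting, rebalancing, fold assignment, ...) each draw
#' their own sub-seed from the run's master seed and the stage name, so that
#' changing one stage's strategy never perturbs another stage's random draws.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' stage_seed(1, "split")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L))
}

# numeric dosage matrix (rows = individuals) from a genotype tibble whose
# first column is individual_id
geno_matrix <- function(geno) {
  stopifnot(is.data.frame(geno), "individual_id" %in% names(geno))
  ids <- as.character(geno$individual_id)
  if (anyDuplicated(ids)) abort("duplicate individual ids in genotype table")
  m <- as.matrix(geno[setdiff(names(geno), "individual_id")])
  storage.mode(m) <- "double"
  bad <- m[!is.na(m)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    abort("genotype dosages must be 0, 1, 2 or NA")
  }
  rownames(m) <- ids
  m
}

# inverse of geno_matrix()
geno_tibble <- function(m) {
  out <- as_tibble(m)
  out <- tibble(individual_id = rownames(m)) %>% dplyr::bind_cols(out)
  out
}

check_fraction <- function(x, name, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 &&
    (if (upper_open) x < 1 else x <= 1)
  if (!ok) abort(sprintf("`%s` must be a fraction in [0, %s", name,
                         if (upper_open) "1)" else "1]"))
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x) &&
    (if (positive) x >= 1 else x >= 0)
  if (!ok) abort(sprintf("`%s` must be a %s integer", name,
                         if (positive) "positive" else "non-negative"))
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
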