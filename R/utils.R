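`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package operations do not perturb the global random stream.
#' @noRd
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Internal node tagging: drugs and effects live in disjoint id namespaces so
# the same opaque string may serve as a drug id and an effect id without the
# partite sets intersecting.
tag_drug <- function(id) paste0("drug:", id)
tag_effect <- function(id) paste0("effect:", id)

untag_class <- function(tagged) sub(":.*$", "", tagged)
untag_id <- function(tagged) sub("^(drug|effect):", "", tagged)

pair_key <- function(drug_id, effect_id) paste(drug_id, effect_id, sep = "\r")

is_scalar_character <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
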