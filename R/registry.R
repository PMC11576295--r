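#' Instrument registry for the flourishing item pool
#'
#' The default registry declares the four flourishing questionnaires analysed
#' jointly as one 47-item pool:
#'
#' * **MHC-SF** (14 items, 0--5): facets EWB (3), SWB (5), PWB (6)
#' * **PERMA**-Profiler, 15-item core (0--10): facets P, E, R, M, A (3 each)
#' * **FS** Flourishing Scale (8 items, 1--7): unidimensional
#' * **WBCF** Wellbeing Conceptual Framework (10 items, mixed 0--4 / 0--3 /
#'   0--10 scales): facets PC (6, one reverse-coded item) and PF (4),
#'   the two-factor solution
#'
#' Item wording is deliberately not stored (the questionnaires are
#' copyrighted); items are identified as `INSTRUMENT-FACET-index`, e.g.
#' `MHC-SF-SWB-4`.
#'
#' @return An object of class `ipv_registry`: a data frame with one row per
#'   item and columns `item_id`, `instrument`, `facet`, `index`, `min_code`,
#'   `max_code`, `reverse`.
#' @export
#' @examples
#' reg <- default_registry()
#' nrow(reg)            # 47
#' table(reg$instrument)
default_registry <- function() {
  rows <- list(
    list("MHC-SF", "EWB", 3L, 0L, 5L, character(0)),
    list("MHC-SF", "SWB", 5L, 0L, 5L, character(0)),
    list("MHC-SF", "PWB", 6L, 0L, 5L, character(0)),
    list("PERMA",  "P",   3L, 0L, 10L, character(0)),
    list("PERMA",  "E",   3L, 0L, 10L, character(0)),
    list("PERMA",  "R",   3L, 0L, 10L, character(0)),
    list("PERMA",  "M",   3L, 0L, 10L, character(0)),
    list("PERMA",  "A",   3L, 0L, 10L, character(0)),
    list("FS",     "FS",  8L, 1L, 7L, character(0))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    idx <- seq_len(r[[3]])
    data.frame(
      item_id    = if (r[[1]] == r[[2]]) paste(r[[1]], idx, sep = "-")
                   else paste(r[[1]], r[[2]], idx, sep = "-"),
      instrument = r[[1]],
      facet      = r[[2]],
      index      = idx,
      min_code   = r[[4]],
      max_code   = r[[5]],
      reverse    = FALSE,
      stringsAsFactors = FALSE
    )
  }))
  # WBCF mixes response formats within its facets: most items 0-4 agreement,
  # emotional stability and vitality 0-3 frequency, positive emotions 0-10.
  wbcf <- data.frame(
    item_id    = c(paste("WBCF-PC", 1:6, sep = "-"),
                   paste("WBCF-PF", 1:4, sep = "-")),
    instrument = "WBCF",
    facet      = rep(c("PC", "PF"), c(6L, 4L)),
    index      = c(1:6, 1:4),
    min_code   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    max_code   = c(4L, 4L, 3L, 3L, 10L, 4L, 4L, 4L, 4L, 4L),
    reverse    = c(FALSE, TRUE, rep(FALSE, 8L)),  # WBCF-PC-2 is reverse-keyed
    stringsAsFactors = FALSE
  )
  out <- rbind(out, wbcf)
  rownames(out) <- NULL
  class(out) <- c("ipv_registry", "data.frame")
  validate_registry(out)
}

known_instruments <- c("MHC-SF", "PERMA", "FS", "WBCF")

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  need <- c("item_id", "instrument", "facet", "index",
            "min_code", "max_code", "reverse")
  missing_cols <- setdiff(need, names(reg))
  if (length(missing_cols))
    stop("registry lacks columns: ", paste(missing_cols, collapse = ", "))
  dup <- reg$item_id[duplicated(reg$item_id)]
  if (length(dup))
    stop("duplicate item id(s) in registry: ", paste(unique(dup), collapse = ", "))
  if (anyNA(reg$min_code) || anyNA(reg$max_code))
    stop("item without a response range")
  if (any(reg$min_code >= reg$max_code))
    stop("response range must satisfy min_code < max_code")
  bad <- setdiff(unique(reg$instrument), known_instruments)
  if (length(bad))
    stop("unknown instrument name(s): ", paste(bad, collapse = ", "))
  reg
}

#' Load an instrument registry from a YAML or JSON config
#'
#' The config maps `instrument -> facet -> {items, range, reverse}` where
#' `items` is either an item count (ids are generated as
#' `INSTRUMENT-FACET-i`) or an explicit vector of item ids, `range` is a
#' two-integer `[min, max]` response range (either per facet, or a list of
#' one range per item for facets mixing response formats), and `reverse`
#' optionally lists reverse-keyed item ids.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `ipv_registry` (see [default_registry()]).
#' @export
load_registry <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  rows <- list()
  for (inst in names(cfg)) {
    for (fac in names(cfg[[inst]])) {
      blk <- cfg[[inst]][[fac]]
      if (is.null(blk$range)) stop("facet ", inst, "-", fac, ": item without range")
      items <- blk$items
      ids <- if (is.numeric(items) && length(items) == 1L) {
        if (inst == fac) paste(inst, seq_len(items), sep = "-")
        else paste(inst, fac, seq_len(items), sep = "-")
      } else {
        as.character(unlist(items))
      }
      rng <- blk$range
      if (is.matrix(rng)) {                  # per-item ranges via JSON
        mins <- as.integer(rng[, 1]); maxs <- as.integer(rng[, 2])
      } else if (is.list(rng)) {             # per-item ranges via YAML
        mins <- vapply(rng, function(r) as.integer(unlist(r)[1]), integer(1))
        maxs <- vapply(rng, function(r) as.integer(unlist(r)[2]), integer(1))
      } else {
        rng <- as.integer(unlist(rng))
        if (length(rng) != 2L) stop("facet ", inst, "-", fac, ": range must be [min, max]")
        mins <- rng[1]; maxs <- rng[2]
      }
      if (length(mins) == 1L) { mins <- rep(mins, length(ids)); maxs <- rep(maxs, length(ids)) }
      if (length(mins) != length(ids))
        stop("facet ", inst, "-", fac, ": one range per item required")
      rev_ids <- as.character(unlist(blk$reverse))
      rows[[length(rows) + 1L]] <- data.frame(
        item_id = ids, instrument = inst, facet = fac,
        index = seq_along(ids), min_code = mins, max_code = maxs,
        reverse = ids %in% rev_ids, stringsAsFactors = FALSE
      )
    }
  }
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  class(reg) <- c("ipv_registry", "data.frame")
  validate_registry(reg)
}

#' @export
print.ipv_registry <- function(x, ...) {
  cat("<ipv_registry> ", nrow(x), " items, ",
      length(unique(x$instrument)), " instruments, ",
      length(unique(paste(x$instrument, x$facet))), " facets\n", sep = "")
  agg <- stats::aggregate(item_id ~ instrument + facet, data = as.data.frame(x),
                          FUN = length)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Facet ids of a registry, in registry order
#' @param registry An `ipv_registry`.
#' @return Character vector of `instrument.facet` labels (unique, ordered).
#' @export
registry_facets <- function(registry) {
  unique(paste(registry$instrument, registry$facet, sep = "."))
}

#' Flip reverse-keyed items
#'
#' Recoding maps a raw response `x` to `max_code + min_code - x` for every
#' item flagged `reverse` in the registry. Applying it twice restores the
#' input (involution).
#'
#' @param data Respondent x item data frame or matrix, columns named by
#'   registry item ids.
#' @param registry An `ipv_registry`.
#' @return `data` with reverse-keyed columns recoded.
#' @export
recode_reversed <- function(data, registry) {
  rev_items <- intersect(registry$item_id[registry$reverse], colnames(data))
  for (it in rev_items) {
    r <- registry[registry$item_id == it, ]
    data[[it]] <- r$max_code + r$min_code - data[[it]]
  }
  data
}

#' Validate (and reverse-code) a response matrix against a registry
#'
#' Checks that every registry item is present exactly once, that there are no
#' missing cells (the reference design is forced-response), and that every
#' value is an integer code inside its item's response range. Reverse-keyed
#' items are then recoded as `max_code + min_code - x`.
#'
#' @param data Respondent x item data frame (or matrix) of integer codes,
#'   columns named by item ids.
#' @param registry An `ipv_registry`.
#' @return A data frame in registry column order with reverse-keyed items
#'   recoded and attribute `validated = TRUE`.
#' @export
validate_responses <- function(data, registry) {
  data <- as.data.frame(data)
  unknown <- setdiff(colnames(data), registry$item_id)
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(registry$item_id, colnames(data))
  if (length(absent))
    stop("missing item column(s): ", paste(absent, collapse = ", "))
  data <- data[, registry$item_id, drop = FALSE]
  if (anyNA(data))
    stop("missing cells are not allowed (forced-response design)")
  for (i in seq_len(nrow(registry))) {
    x <- data[[registry$item_id[i]]]
    if (any(x != round(x)))
      stop("non-integer codes in item ", registry$item_id[i])
    if (any(x < registry$min_code[i] | x > registry$max_code[i]))
      stop("out-of-range code in item ", registry$item_id[i],
           " (allowed ", registry$min_code[i], "-", registry$max_code[i], ")")
  }
  out <- recode_reversed(data, registry)
  attr(out, "validated") <- TRUE
  out
}

#' Score subscale composites
#'
#' Each facet composite is the mean of its item scores. With
#' `standardize_items` on, each item is z-scored across respondents before
#' averaging; this is required whenever the response ranges differ within a
#' facet, and is therefore the default for the WBCF (5-, 4- and 11-point
#' items in one pool) while the other instruments default to raw-scale means.
#'
#' @param data Validated response data (see [validate_responses()]).
#' @param registry An `ipv_registry`.
#' @param standardize_items `NULL` (per-instrument default: `TRUE` for any
#'   facet mixing response ranges, else `FALSE`), or a single logical applied
#'   to every facet.
#' @return A list of class `ipv_scores`: `composites` (respondent x facet
#'   data frame) and `summary` (facet, instrument, n_items, M, SD).
#' @export
score_subscales <- function(data, registry, standardize_items = NULL) {
  data <- as.data.frame(data)
  facs <- registry_facets(registry)
  comps <- matrix(NA_real_, nrow(data), length(facs),
                  dimnames = list(NULL, facs))
  n_items <- integer(length(facs))
  for (j in seq_along(facs)) {
    sel <- paste(registry$instrument, registry$facet, sep = ".") == facs[j]
    items <- registry$item_id[sel]
    n_items[j] <- length(items)
    x <- as.matrix(data[, items, drop = FALSE])
    mixed <- length(unique(registry$min_code[sel])) > 1L ||
      length(unique(registry$max_code[sel])) > 1L
    std <- if (is.null(standardize_items)) mixed else isTRUE(standardize_items)
    if (std) {
      sds <- apply(x, 2, stats::sd)
      if (any(sds == 0))
        stop("zero-variance item when standardizing: ",
             paste(items[sds == 0], collapse = ", "))
      x <- scale(x)
    }
    comps[, j] <- rowMeans(x)
  }
  comps <- as.data.frame(comps, check.names = FALSE)
  smry <- data.frame(
    facet = facs,
    instrument = registry$instrument[match(facs, paste(registry$instrument,
                                                       registry$facet, sep = "."))],
    n_items = n_items,
    M = vapply(comps, mean, numeric(1)),
    SD = vapply(comps, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(composites = comps, summary = smry), class = "ipv_scores")
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))`, with sample
#' (n-1) variances throughout.
#'
#' @param items Respondent x item matrix or data frame (>= 2 items, >= 3
#'   respondents).
#' @return List with `alpha`, `k` (items), `n` (respondents).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' cronbach_alpha(x + rnorm(100))  # shared row effect -> positive alpha
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  k <- ncol(x); n <- nrow(x)
  if (k < 2L) stop("alpha needs >= 2 items")
  if (n < 3L) stop("alpha needs >= 3 respondents")
  vtot <- stats::var(rowSums(x))
  if (vtot == 0) stop("total-score variance is zero")
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vtot)
  list(alpha = alpha, k = k, n = n)
}

#' Reliability and descriptives table
#'
#' One row per facet: item count, composite mean and SD, and Cronbach's
#' alpha over the facet's items (computed on z-scored items when the facet
#' mixes response ranges, matching the composite).
#'
#' @inheritParams score_subscales
#' @return Data frame with columns `facet`, `instrument`, `n_items`, `M`,
#'   `SD`, `alpha`.
#' @export
reliability_table <- function(data, registry, standardize_items = NULL) {
  sc <- score_subscales(data, registry, standardize_items)
  out <- sc$summary
  out$alpha <- NA_real_
  for (j in seq_len(nrow(out))) {
    sel <- paste(registry$instrument, registry$facet, sep = ".") == out$facet[j]
    items <- registry$item_id[sel]
    if (length(items) < 2L) next
    x <- as.matrix(as.data.frame(data)[, items, drop = FALSE])
    mixed <- length(unique(registry$min_code[sel])) > 1L ||
      length(unique(registry$max_code[sel])) > 1L
    std <- if (is.null(standardize_items)) mixed else isTRUE(standardize_items)
    if (std) x <- scale(x)
    out$alpha[j] <- cronbach_alpha(x)$alpha
  }
  out
}

#' Pearson correlation matrix of subscale composites
#'
#' @param scores An `ipv_scores` object or a numeric data frame/matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(scores) {
  x <- if (inherits(scores, "ipv_scores")) as.matrix(scores$composites)
       else as.matrix(scores)
  if (nrow(x) < 3L) stop("need >= 3 respondents")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  (r + t(r)) / 2
}
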