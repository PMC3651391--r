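# Per-domain normalization of MAPP impact scores.
#
# The optimal MAPP decision threshold differs between MSH6 domains because
# conservation differs: whole-sequence 8.5, PCNA-binding motif 4.1, PWWP
# domain 5.0, MutS domain 4.1. Dividing the raw impact score by the
# threshold of the covering domain puts the decision boundary at 1.0
# everywhere along the sequence.

#' The packaged MSH6 domain map
#'
#' Domain layout of human MSH6 with the per-domain raw MAPP thresholds:
#' PCNA-binding motif (residues 4-11, threshold 4.1), PWWP domain (89-194,
#' threshold 5.0), MutS domain (362-1355, threshold 4.1); positions outside
#' these regions use the whole-sequence threshold 8.5.
#'
#' @return A `codp_domain_map`: list with `default_threshold` and a `domains`
#'   data frame (`name`, `start`, `end`, `threshold`).
#' @export
msh6_domain_map <- function() {
  domain_map(
    domains = data.frame(
      name = c("PCNA-binding motif", "PWWP", "MutS"),
      start = c(4L, 89L, 362L),
      end = c(11L, 194L, 1355L),
      threshold = c(4.1, 5.0, 4.1),
      stringsAsFactors = FALSE
    ),
    default_threshold = 8.5
  )
}

#' Construct a domain map
#'
#' @param domains Data frame with columns `name`, `start`, `end` (1-based,
#'   inclusive, non-overlapping) and `threshold` (> 0).
#' @param default_threshold Raw threshold for positions outside every domain.
#' @return A `codp_domain_map`.
#' @export
domain_map <- function(domains, default_threshold) {
  stopifnot(is.data.frame(domains),
            all(c("name", "start", "end", "threshold") %in% names(domains)))
  if (default_threshold <= 0 || any(domains$threshold <= 0)) {
    stop("codp_invalid_argument: thresholds must be > 0", call. = FALSE)
  }
  if (any(domains$start > domains$end) || any(domains$start < 1)) {
    stop("codp_invalid_argument: domain spans must satisfy 1 <= start <= end",
         call. = FALSE)
  }
  o <- order(domains$start)
  d <- domains[o, , drop = FALSE]
  if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
    stop("codp_invalid_argument: domains overlap", call. = FALSE)
  }
  structure(list(domains = d, default_threshold = default_threshold),
            class = "codp_domain_map")
}

#' @export
print.codp_domain_map <- function(x, ...) {
  cat("codp_domain_map (default threshold", x$default_threshold, "):\n")
  print(x$domains, row.names = FALSE)
  invisible(x)
}

#' Domain covering a protein position
#'
#' @param position Integer vector of 1-based protein positions.
#' @param map A `codp_domain_map` (default: the MSH6 map).
#' @return Character vector: the covering domain's name, or
#'   `"inter-domain"` for positions outside every entry.
#' @examples
#' domain_of(c(4, 100, 250))
#' @export
domain_of <- function(position, map = msh6_domain_map()) {
  if (any(!is.finite(position)) || any(position < 1)) {
    stop("codp_invalid_argument: position must be >= 1", call. = FALSE)
  }
  d <- map$domains
  vapply(position, function(p) {
    hit <- which(p >= d$start & p <= d$end)
    if (length(hit)) d$name[hit[1L]] else "inter-domain"
  }, character(1))
}

.threshold_at <- function(position, map) {
  d <- map$domains
  vapply(position, function(p) {
    hit <- which(p >= d$start & p <= d$end)
    if (length(hit)) d$threshold[hit[1L]] else map$default_threshold
  }, numeric(1))
}

#' Normalize a raw MAPP impact score
#'
#' Divides the raw score by the threshold of the domain covering its
#' position, so that 1.0 is the pathogenicity decision boundary everywhere.
#'
#' @param raw_score Non-negative raw MAPP impact score(s).
#' @param position Protein position(s), 1-based.
#' @param map A `codp_domain_map`.
#' @return Normalized score(s).
#' @examples
#' normalize_mapp(4.1, 500)   # MutS domain -> 1.0
#' normalize_mapp(8.5, 250)   # inter-domain -> 1.0
#' @export
normalize_mapp <- function(raw_score, position, map = msh6_domain_map()) {
  if (any(!is.finite(raw_score)) || any(raw_score < 0)) {
    stop("codp_invalid_argument: raw MAPP scores must be finite and >= 0",
         call. = FALSE)
  }
  raw_score / .threshold_at(position, map)
}

#' Read / write a domain map as JSON
#'
#' Format: `{"default_threshold": 8.5, "domains": [{"name", "start", "end",
#' "threshold"}, ...]}`. The packaged MSH6 map ships under
#' `system.file("extdata", "msh6_domain_map.json", package = "codp")`.
#'
#' @param path JSON file path.
#' @return `read_domain_map()`: a `codp_domain_map`.
#' @export
read_domain_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  domain_map(as.data.frame(x$domains), x$default_threshold)
}

#' @rdname read_domain_map
#' @param map A `codp_domain_map` to serialize.
#' @export
write_domain_map <- function(map, path) {
  jsonlite::write_json(
    list(default_threshold = map$default_threshold, domains = map$domains),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
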