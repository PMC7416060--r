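# Region-to-network membership and the reduction of framewise correlation
# matrices to the 12 pair-averaged connection weights: within and between
# the three intrinsic networks (DMN, CEN, SN) and between each network and
# the two bilateral subcortical seed sets (Amyg, NAcc).

NETWORK_LABELS <- c("DMN", "CEN", "SN", "Amyg", "NAcc", "other")

#' The 12 connection types
#'
#' Within-network (WithinDMN, WithinCEN, WithinSN), between-network
#' (DMN-CEN, DMN-SN, CEN-SN), and seed-to-network (Amyg-DMN, Amyg-CEN,
#' Amyg-SN, NAcc-DMN, NAcc-CEN, NAcc-SN) connection labels.
#'
#' @return Character vector of length 12.
#' @export
connection_types <- function() {
  c("WithinDMN", "WithinCEN", "WithinSN",
    "DMN-CEN", "DMN-SN", "CEN-SN",
    "Amyg-DMN", "Amyg-CEN", "Amyg-SN",
    "NAcc-DMN", "NAcc-CEN", "NAcc-SN")
}

#' Region-to-network membership
#'
#' Validates and normalizes a membership table. Labels are matched
#' case-insensitively against DMN, CEN, SN, Amyg, NAcc and other; unknown
#' labels are mapped to `other` with a warning. Regions labeled `other`
#' participate only in whole-graph topology, never in connection
#' summaries.
#'
#' @param region_id Character or numeric region identifiers (unique).
#' @param network Network label per region.
#' @return Data frame of class `roi_membership` with columns `region_id`
#'   and `network`.
#' @export
roi_membership <- function(region_id, network) {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id))
    stop("duplicated region ids: ",
         paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  if (length(region_id) != length(network))
    stop("region_id and network must have equal length")
  idx <- match(toupper(as.character(network)), toupper(NETWORK_LABELS))
  if (anyNA(idx)) {
    bad <- unique(network[is.na(idx)])
    warning("unknown network label(s) mapped to 'other': ",
            paste(bad, collapse = ", "))
    idx[is.na(idx)] <- which(NETWORK_LABELS == "other")
  }
  out <- data.frame(region_id = region_id,
                    network = NETWORK_LABELS[idx],
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_membership", "data.frame")
  out
}

# Split a connection type into its two member sets.
connection_parts <- function(type) {
  if (grepl("^Within", type)) {
    net <- sub("^Within", "", type)
    list(a = net, b = net)
  } else {
    parts <- strsplit(type, "-", fixed = TRUE)[[1]]
    list(a = parts[1], b = parts[2])
  }
}

#' Enumerate the region pairs of a connection type
#'
#' Within-network types yield all n(n-1)/2 unordered pairs; between-set
#' types yield all n_A x n_B pairs. The order is deterministic (row-major
#' in the membership order) and duplicate-free.
#'
#' @param membership A [roi_membership].
#' @param type One of [connection_types()].
#' @return List with `pairs` (2-column character matrix of region ids)
#'   and `n_conn` (the pair count N_Conn).
#' @export
enumerate_pairs <- function(membership, type) {
  stopifnot(inherits(membership, "roi_membership"))
  if (!type %in% connection_types())
    stop("unknown connection type: ", type)
  parts <- connection_parts(type)
  a <- membership$region_id[membership$network == parts$a]
  b <- membership$region_id[membership$network == parts$b]
  if (parts$a == parts$b) {
    if (length(a) < 2)
      stop("empty network: '", parts$a,
           "' needs at least 2 regions for within-network pairs")
    idx <- which(upper.tri(matrix(0, length(a), length(a))), arr.ind = TRUE)
    pairs <- cbind(a[idx[, 1]], a[idx[, 2]])
  } else {
    if (length(a) == 0 || length(b) == 0)
      stop("empty network: '",
           if (length(a) == 0) parts$a else parts$b,
           "' has no regions")
    pairs <- cbind(rep(a, each = length(b)), rep(b, length(a)))
  }
  list(pairs = pairs, n_conn = nrow(pairs))
}

#' Pair-averaged connection weights per frame
#'
#' Reduces a framewise correlation stack to the 12 connection summaries:
#' for every frame and connection type, the arithmetic mean of the
#' constituent pairs' correlation weights.
#'
#' @param R A [dcc_series] or a `p x p x T` array with region dimnames.
#' @param membership A [roi_membership] covering the array's regions.
#' @return Object of class `connection_summaries`: 12 x T numeric matrix
#'   (rownames are connection types) with attribute `n_conn`.
#' @export
summarize_series <- function(R, membership) {
  stopifnot(inherits(membership, "roi_membership"))
  arr <- if (inherits(R, "dcc_series")) R$R else R
  if (length(dim(arr)) != 3 || dim(arr)[1] != dim(arr)[2])
    stop("R must be a p x p x T array")
  regions <- dimnames(arr)[[1]]
  if (is.null(regions)) stop("R must carry region ids as dimnames")
  used <- membership$region_id[membership$network != "other"]
  missing_ids <- setdiff(used, regions)
  if (length(missing_ids))
    stop("membership regions absent from series: ",
         paste(missing_ids, collapse = ", "))
  p <- dim(arr)[1]
  Tn <- dim(arr)[3]
  flat <- matrix(arr, p * p, Tn)
  types <- connection_types()
  out <- matrix(NA_real_, length(types), Tn,
                dimnames = list(types, NULL))
  n_conn <- integer(length(types))
  names(n_conn) <- types
  for (k in seq_along(types)) {
    ep <- enumerate_pairs(membership, types[k])
    i <- match(ep$pairs[, 1], regions)
    j <- match(ep$pairs[, 2], regions)
    lin <- i + (j - 1L) * p
    out[k, ] <- if (length(lin) == 1) flat[lin, ] else colMeans(flat[lin, , drop = FALSE])
    n_conn[k] <- ep$n_conn
  }
  structure(out, n_conn = n_conn, class = c("connection_summaries", "matrix"))
}
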