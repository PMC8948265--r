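#' Construct a branching network
#'
#' A network encodes the geometry of a branching 3D channel system as
#' per-branch piecewise-linear incline functions phi(x) over arc length.
#' Each junction row carries: `id`, the `branch` it belongs to, its
#' arc-length position `x` (m) from the network start, the local incline
#' `phi_deg`, a `kind` (`"waypoint"`, `"turn"` or `"terminal"`), the child
#' branch ids rooted at it (turns only) and the arc positions of adjacent
#' untargeted channel mouths (`parallel_offsets`, m). Because the targeting
#' simulation integrates a scalar arc-length position, geometry is
#' intrinsically 1-D along the channel centerline; where a turn is followed
#' by another turn, each branch carries its own incline function.
#'
#' @param junctions A data.frame with columns `id` (character), `branch`
#'   (character), `x` (m), `phi_deg`, `kind`, and list-columns `children`
#'   (character vectors) and `parallel_offsets` (numeric, m). Missing
#'   list-columns default to empty.
#' @param target Target branch id.
#' @param channel_diameter Channel diameter (m), informational. Default
#'   6e-4.
#' @param validate If `TRUE` (default) run [validate_network()] and error on
#'   violations.
#' @return A list of class `uw_network`.
#' @seealso [read_network()], [validate_network()], [find_path()]
#' @export
uw_network <- function(junctions, target, channel_diameter = 6e-4,
                       validate = TRUE) {
  j <- as.data.frame(junctions, stringsAsFactors = FALSE)
  if (is.null(j$children)) j$children <- replicate(nrow(j), character(0), simplify = FALSE)
  if (is.null(j$parallel_offsets)) j$parallel_offsets <- replicate(nrow(j), numeric(0), simplify = FALSE)
  j$id <- as.character(j$id)
  j$branch <- as.character(j$branch)
  j$kind <- as.character(j$kind)
  net <- structure(list(junctions = j, target = as.character(target),
                        channel_diameter = channel_diameter),
                   class = "uw_network")
  if (validate) {
    errs <- validate_network(net)
    if (length(errs))
      uw_stop(paste0("invalid network:\n  - ", paste(errs, collapse = "\n  - ")),
              "uw_network_error")
  }
  net
}

.branch_ids <- function(net) unique(net$junctions$branch)

# parent branch of each branch (NA for root): the branch of the turn
# junction listing it as a child
.branch_parents <- function(net) {
  j <- net$junctions
  parents <- stats::setNames(rep(NA_character_, length(.branch_ids(net))),
                             .branch_ids(net))
  for (i in seq_len(nrow(j))) {
    for (ch in j$children[[i]]) parents[ch] <- j$branch[i]
  }
  parents
}

#' Validate a network
#'
#' Checks every structural invariant and returns a character vector naming
#' each violation (empty when valid): non-monotonic arc positions along a
#' branch (`monotonicity`), child branch ids that do not exist (`orphan
#' branch`), junctions on branches reachable from nowhere (`orphan
#' junction`), a missing or unreachable target (`missing target`), multiple
#' or no root branches, incline angles outside (-90, 90), and turn
#' junctions with fewer than two children.
#'
#' @param net A `uw_network` (validated or not).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_network <- function(net) {
  j <- net$junctions
  errs <- character(0)
  if (any(j$x < 0)) errs <- c(errs, "monotonicity: negative arc position x")
  if (any(j$phi_deg <= -90 | j$phi_deg >= 90))
    errs <- c(errs, "incline angles must lie strictly within (-90, 90) degrees")
  if (anyDuplicated(j$id)) errs <- c(errs, "duplicate junction ids")
  for (b in .branch_ids(net)) {
    x <- j$x[j$branch == b]
    if (any(diff(x) <= 0))
      errs <- c(errs, sprintf("monotonicity: arc positions not strictly increasing along branch '%s'", b))
  }
  all_children <- unique(unlist(j$children))
  missing_child <- setdiff(all_children, .branch_ids(net))
  if (length(missing_child))
    errs <- c(errs, sprintf("orphan branch: child branch '%s' has no junctions",
                            missing_child))
  parents <- .branch_parents(net)
  roots <- intersect(names(parents)[is.na(parents)], .branch_ids(net))
  if (length(roots) == 0L) {
    errs <- c(errs, "network has no start branch (cyclic parentage?)")
  } else {
    # the true start is the root branch holding the junction closest to x = 0;
    # any other root is unreachable
    start_branch <- j$branch[which.min(j$x)]
    root <- if (start_branch %in% roots) start_branch else roots[1]
    reach <- root
    repeat {
      nxt <- unique(unlist(j$children[j$branch %in% reach]))
      new <- setdiff(intersect(nxt, .branch_ids(net)), reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    orphan <- setdiff(.branch_ids(net), reach)
    if (length(orphan))
      errs <- c(errs, sprintf("orphan junction: branch '%s' unreachable from start", orphan))
    if (!(net$target %in% .branch_ids(net)) || !(net$target %in% reach))
      errs <- c(errs, sprintf("missing target: branch '%s' absent or unreachable",
                              net$target))
  }
  nch <- vapply(j$children, length, integer(1))
  if (any(j$kind == "turn" & nch < 2))
    errs <- c(errs, "turn junctions must have >= 2 children")
  if (any(j$kind != "turn" & nch > 0))
    errs <- c(errs, "only turn junctions may have children")
  errs
}

#' @export
print.uw_network <- function(x, ...) {
  term <- sum(x$junctions$kind == "terminal")
  cat(sprintf("<uw_network> %d junctions, %d branches, %d terminals, target '%s'\n",
              nrow(x$junctions), length(.branch_ids(x)), term, x$target))
  invisible(x)
}

#' Plan the path from the network start to a target branch
#'
#' Walks the branch-parent relation from the target back to the root. The
#' plan records, in order, each turn junction passed and the child branch
#' chosen there, plus the resulting piecewise-linear incline knots assembled
#' from the per-branch incline functions (the child branch's own phi(x)
#' takes over at each turn).
#'
#' @param net A `uw_network`.
#' @param target Target branch id; defaults to `net$target`.
#' @return A list of class `uw_path`: `branches` (root-to-target branch
#'   ids), `turns` (data.frame `junction_id`, `x`, `chosen`, list-column
#'   `parallel_offsets`), `knots` (data.frame `x`, `phi_deg`), `length`
#'   (terminal arc position, m).
#' @export
find_path <- function(net, target = net$target) {
  parents <- .branch_parents(net)
  if (!(target %in% names(parents)))
    uw_stop(sprintf("target branch '%s' not in network", target), "uw_config_error")
  chain <- target
  while (!is.na(parents[chain[1]])) chain <- c(parents[chain[1]], chain)
  j <- net$junctions
  turn_list <- list()
  knots <- data.frame(x = numeric(0), phi_deg = numeric(0))
  for (i in seq_along(chain)) {
    b <- chain[i]
    jb <- j[j$branch == b, ]
    jb <- jb[order(jb$x), ]
    if (i < length(chain)) {
      # stop this branch's knots at the turn leading to the next branch
      nxt <- chain[i + 1]
      has_child <- vapply(jb$children, function(ch) nxt %in% ch, logical(1))
      ti <- which(has_child)[1]
      if (is.na(ti))
        uw_stop("inconsistent path: turn to child branch not found", "uw_network_error")
      turn_row <- jb[ti, ]
      turn_list[[length(turn_list) + 1L]] <-
        list(junction_id = turn_row$id, x = turn_row$x, chosen = nxt,
             parallel_offsets = turn_row$parallel_offsets[[1]])
      jb <- jb[jb$x <= turn_row$x, ]
    }
    knots <- rbind(knots, data.frame(x = jb$x, phi_deg = jb$phi_deg))
  }
  turns <- data.frame(
    junction_id = vapply(turn_list, `[[`, "", "junction_id"),
    x = vapply(turn_list, `[[`, 0, "x"),
    chosen = vapply(turn_list, `[[`, "", "chosen"),
    stringsAsFactors = FALSE)
  turns$parallel_offsets <- lapply(turn_list, `[[`, "parallel_offsets")
  # at a switch point the child branch's own value takes over
  knots <- knots[!duplicated(knots$x, fromLast = TRUE), ]
  knots <- knots[order(knots$x), ]
  structure(list(branches = chain, turns = turns, knots = knots,
                 length = max(knots$x)),
            class = "uw_path")
}

#' Incline angle at an arc position along a path
#'
#' Linear interpolation between junction knots: exact at junctions,
#' continuous piecewise-linear between them.
#'
#' @param net A `uw_network`.
#' @param path A `uw_path` from [find_path()].
#' @param x Arc positions (m), vectorized; must lie in `[0, path end]`.
#' @return Incline angles (degrees).
#' @export
incline_at <- function(net, path, x) {
  if (any(x < path$knots$x[1] - 1e-12 | x > path$length + 1e-12))
    uw_stop("position x outside the path", "uw_domain_error")
  .incline_lookup(path, x)
}

# internal lookup used by the simulator: clamps beyond-terminal and
# behind-start queries to the end values (constant extrapolation)
.incline_lookup <- function(path, x) {
  k <- path$knots
  if (nrow(k) == 1L) return(rep(k$phi_deg, length(x)))
  stats::approx(k$x, k$phi_deg, xout = pmin(pmax(x, k$x[1]), k$x[nrow(k)]),
                method = "linear", ties = "ordered")$y
}

# ---- serialization ---------------------------------------------------------

#' Read / write a network (JSON or CSV)
#'
#' JSON schema: `{junctions: [{id, branch, x_mm, phi_deg, kind, children,
#' parallel_offsets_mm}], target, channel_diameter_mm}`. The CSV dialect has
#' one junction per row with the same fields, `children` and
#' `parallel_offsets_mm` as semicolon-joined strings, header required.
#' Format chosen by file extension (`.json` / `.csv`).
#'
#' @param net A `uw_network`.
#' @param path File path ending in `.json` or `.csv`.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a validated `uw_network`.
#' @export
write_network <- function(net, path) {
  j <- net$junctions
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_len(nrow(j)), function(i) list(
      id = j$id[i], branch = j$branch[i], x_mm = j$x[i] * 1e3,
      phi_deg = j$phi_deg[i], kind = j$kind[i],
      children = as.list(j$children[[i]]),
      parallel_offsets_mm = as.list(j$parallel_offsets[[i]] * 1e3)))
    jsonlite::write_json(list(junctions = recs, target = net$target,
                              channel_diameter_mm = net$channel_diameter * 1e3),
                         path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- data.frame(id = j$id, branch = j$branch, x_mm = j$x * 1e3,
                    phi_deg = j$phi_deg, kind = j$kind,
                    children = vapply(j$children, paste, "", collapse = ";"),
                    parallel_offsets_mm = vapply(j$parallel_offsets, function(p)
                      paste(format(p * 1e3, digits = 17), collapse = ";"), ""),
                    target = net$target,
                    channel_diameter_mm = net$channel_diameter * 1e3)
    utils::write.csv(d, path, row.names = FALSE)
  } else uw_stop("unsupported network file extension", "uw_format_error")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path)
    recs <- obj$junctions
    j <- data.frame(
      id = vapply(recs, function(r) as.character(r$id), ""),
      branch = vapply(recs, function(r) as.character(r$branch), ""),
      x = vapply(recs, function(r) as.numeric(r$x_mm), 0) * 1e-3,
      phi_deg = vapply(recs, function(r) as.numeric(r$phi_deg), 0),
      kind = vapply(recs, function(r) as.character(r$kind), ""),
      stringsAsFactors = FALSE)
    j$children <- lapply(recs, function(r) as.character(unlist(r$children)))
    j$parallel_offsets <- lapply(recs, function(r)
      as.numeric(unlist(r$parallel_offsets_mm)) * 1e-3)
    uw_network(j, target = obj$target,
               channel_diameter = as.numeric(obj$channel_diameter_mm) * 1e-3)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(children = "character",
                                        parallel_offsets_mm = "character"))
    split_f <- function(s) if (is.na(s) || s == "") character(0) else strsplit(s, ";")[[1]]
    j <- data.frame(id = as.character(d$id), branch = as.character(d$branch),
                    x = d$x_mm * 1e-3, phi_deg = d$phi_deg, kind = d$kind,
                    stringsAsFactors = FALSE)
    j$children <- lapply(d$children, split_f)
    j$parallel_offsets <- lapply(d$parallel_offsets_mm,
                                 function(s) as.numeric(split_f(s)) * 1e-3)
    uw_network(j, target = d$target[1],
               channel_diameter = d$channel_diameter_mm[1] * 1e-3)
  } else uw_stop("unsupported network file extension", "uw_format_error")
}
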