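# Signed-rank reference profiles and compound reference sets.
#
# A reference profile encodes one compound-treatment experiment as a signed
# ranking of every probe on the platform: the magnitude of the rank is the
# position of the probe when probes are ordered by the strength of their
# differential expression (N = most extreme), and the sign is the direction
# of regulation. A database is a probe x profile integer matrix plus a
# metadata table mapping each profile to its compound.

#' Validate a probe universe
#'
#' The probe universe fixes the vocabulary and ordering of a reference
#' database: a vector of unique probe identifiers whose length N is the
#' profile length. All profiles and signatures scored against a database
#' must draw their probes from its universe.
#'
#' @param probe_ids Character vector of probe identifiers.
#' @return The validated character vector, invisibly classed as used.
#' @export
probe_universe <- function(probe_ids) {
  probe_ids <- as.character(probe_ids)
  if (anyDuplicated(probe_ids)) {
    dup <- unique(probe_ids[duplicated(probe_ids)])
    abort(
      c("Probe universe must not contain duplicates.",
        x = paste0("Duplicated: ", paste(head(dup, 5), collapse = ", "))),
      class = "connmap_error_universe"
    )
  }
  if (length(probe_ids) < 2) {
    abort("Probe universe must contain at least 2 probes.",
          class = "connmap_error_universe")
  }
  probe_ids
}

#' Build a signed-rank reference profile from differential statistics
#'
#' Converts one experiment's signed differential-expression statistics into
#' a signed-rank profile over the universe: probes are ordered by descending
#' absolute statistic, the most extreme probe receives magnitude N, the
#' least extreme magnitude 1, and each rank carries the sign of its
#' statistic. Ties in absolute statistic are broken deterministically by
#' universe order (the earlier probe gets the larger magnitude); a zero
#' statistic is given a positive sign by convention.
#'
#' @param diff_stats Data frame with columns `probe_id` and `stat` (a signed
#'   real statistic, e.g. a moderated t or a log fold change), covering
#'   every probe of the universe exactly once.
#' @param universe Character vector of probe identifiers (see
#'   [probe_universe()]).
#' @return A tibble with columns `probe_id` and `signed_rank`, in universe
#'   order. The magnitudes of `signed_rank` are exactly the permutation
#'   1..N.
#' @examples
#' u <- c("A", "B", "C")
#' build_profile(tibble::tibble(probe_id = u, stat = c(2, -1, 0.5)), u)
#' @export
build_profile <- function(diff_stats, universe) {
  universe <- probe_universe(universe)
  stopifnot(is.data.frame(diff_stats))
  if (!all(c("probe_id", "stat") %in% names(diff_stats))) {
    abort("`diff_stats` needs columns `probe_id` and `stat`.",
          class = "connmap_error_profile")
  }
  if (anyDuplicated(diff_stats$probe_id)) {
    dup <- unique(diff_stats$probe_id[duplicated(diff_stats$probe_id)])
    abort(
      c("Each probe may appear only once in `diff_stats`.",
        x = paste0("Duplicated: ", paste(head(dup, 5), collapse = ", "))),
      class = "connmap_error_profile"
    )
  }
  missing <- setdiff(universe, diff_stats$probe_id)
  extra <- setdiff(diff_stats$probe_id, universe)
  if (length(missing) || length(extra)) {
    abort(
      c("`diff_stats` must cover the universe exactly.",
        x = if (length(missing))
          paste0("Missing probes: ", paste(head(missing, 5), collapse = ", ")),
        x = if (length(extra))
          paste0("Unknown probes: ", paste(head(extra, 5), collapse = ", "))),
      class = "connmap_error_profile"
    )
  }
  s <- diff_stats$stat[match(universe, diff_stats$probe_id)]
  n <- length(universe)
  ord <- order(-abs(s), seq_len(n))        # ties: earlier probe ranks higher
  mag <- integer(n)
  mag[ord] <- n:1L
  sgn <- ifelse(s < 0, -1L, 1L)            # sign(0) := +1
  tibble(probe_id = universe, signed_rank = as.integer(sgn * mag))
}

#' Construct a reference database
#'
#' Bundles a signed-rank matrix with its profile metadata. Profiles sharing
#' a compound form that compound's reference set; the set's cardinality is
#' its setsize.
#'
#' @param ranks Integer matrix, probes x profiles; row names are probe
#'   identifiers, column names profile identifiers. Each column's
#'   magnitudes must be a permutation of 1..N.
#' @param meta Data frame with columns `profile_id` and `compound`
#'   (optionally `cell_line`, `dose`); one row per column of `ranks`.
#' @return An object of class `ref_db` with elements `universe`, `ranks`
#'   and `meta`.
#' @export
ref_db <- function(ranks, meta) {
  ranks <- as.matrix(ranks)
  storage.mode(ranks) <- "integer"
  meta <- as_tibble(meta)
  db <- structure(
    list(universe = probe_universe(rownames(ranks)), ranks = ranks,
         meta = meta),
    class = "ref_db"
  )
  validate_ref_db(db)
}

validate_ref_db <- function(db) {
  ranks <- db$ranks
  meta <- db$meta
  if (is.null(colnames(ranks))) {
    abort("Profile matrix must have column names (profile ids).",
          class = "connmap_error_db")
  }
  if (!all(c("profile_id", "compound") %in% names(meta))) {
    abort("Metadata needs columns `profile_id` and `compound`.",
          class = "connmap_error_db")
  }
  unknown <- setdiff(meta$profile_id, colnames(ranks))
  orphan <- setdiff(colnames(ranks), meta$profile_id)
  if (length(unknown) || length(orphan)) {
    abort(
      c("Metadata and profile matrix disagree on profile ids.",
        x = if (length(unknown))
          paste0("In metadata only: ", paste(head(unknown, 5), collapse = ", ")),
        x = if (length(orphan))
          paste0("In matrix only: ", paste(head(orphan, 5), collapse = ", "))),
      class = "connmap_error_db"
    )
  }
  if (anyDuplicated(meta$profile_id)) {
    abort("Duplicate profile ids in metadata.", class = "connmap_error_db")
  }
  n <- nrow(ranks)
  target <- seq_len(n)
  for (j in seq_len(ncol(ranks))) {
    m <- sort(abs(ranks[, j]))
    if (!identical(as.integer(m), target)) {
      abort(
        paste0("Profile `", colnames(ranks)[j],
               "`: rank magnitudes are not a permutation of 1..", n, "."),
        class = "connmap_error_db"
      )
    }
  }
  db
}

#' @export
print.ref_db <- function(x, ...) {
  k <- table(x$meta$compound)
  cat("<ref_db> ", length(x$universe), " probes, ",
      ncol(x$ranks), " profiles, ", length(k), " compound sets (setsize ",
      min(k), "-", max(k), ")\n", sep = "")
  invisible(x)
}

#' Number of compound reference sets in a database
#' @param db A `ref_db`.
#' @return Integer count D of distinct compounds.
#' @export
n_ref_sets <- function(db) {
  length(unique(db$meta$compound))
}

#' Reference-set summary of a database
#' @param db A `ref_db`.
#' @return Tibble with columns `compound` and `setsize`.
#' @export
ref_sets <- function(db) {
  db$meta |>
    group_by(.data$compound) |>
    summarise(setsize = n(), .groups = "drop")
}

# Per-compound mean signed-rank matrix (N x D). The connection score of a
# signature to a whole set is linear in the profiles, so the set mean is a
# sufficient statistic for both observed and null set scores.
set_rank_means <- function(db) {
  groups <- split(db$meta$profile_id, db$meta$compound)
  vapply(groups, function(ids) {
    rowMeans(db$ranks[, ids, drop = FALSE])
  }, numeric(nrow(db$ranks)))
}

#' Read / write a reference database
#'
#' The on-disk dialect is two tab-delimited UTF-8 files with header rows: a
#' profile matrix (first column `probe_id`, one integer column per profile)
#' and a metadata table (columns `profile_id`, `compound`, plus any
#' extras). `read_ref_db(write_ref_db(db, ...))` reproduces the database
#' exactly; all invariants are re-validated on load.
#'
#' @param db A `ref_db`.
#' @param profiles_path,metadata_path File paths for the two tables.
#' @return `read_ref_db` returns a `ref_db`; `write_ref_db` returns its
#'   paths invisibly.
#' @export
write_ref_db <- function(db, profiles_path, metadata_path) {
  wide <- as_tibble(db$ranks)
  wide <- tibble(probe_id = db$universe) |> dplyr::bind_cols(wide)
  readr::write_tsv(wide, profiles_path)
  readr::write_tsv(db$meta, metadata_path)
  invisible(c(profiles = profiles_path, metadata = metadata_path))
}

#' @rdname write_ref_db
#' @export
read_ref_db <- function(profiles_path, metadata_path) {
  wide <- readr::read_tsv(profiles_path, show_col_types = FALSE,
                          progress = FALSE)
  if (names(wide)[1] != "probe_id") {
    abort("Profile matrix file must start with a `probe_id` column.",
          class = "connmap_error_db")
  }
  ranks <- as.matrix(wide[-1])
  rownames(ranks) <- wide$probe_id
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  ref_db(ranks, meta)
}
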