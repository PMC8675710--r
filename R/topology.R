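#' Electrode layouts
#'
#' Packaged 10-20 electrode layouts. `deap32` is the 32-channel montage in
#' its native channel order; `seed62` is the 62-channel ESI montage.
#' Electrode names are canonicalized to upper case throughout the package.
#'
#' @param layout_id One of `"deap32"`, `"seed62"`.
#' @return An object of class `eeg_layout`: a list with `layout_id`,
#'   `electrodes` (ordered character vector) and `channel_index`
#'   (named integer vector mapping electrode name to its 1-based column
#'   index in raw arrays).
#' @export
electrode_layout <- function(layout_id) {
  layouts <- list(
    deap32 = c(
      "FP1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
      "P3", "P7", "PO3", "O1", "OZ", "PZ", "FP2", "AF4", "FZ", "F4",
      "F8", "FC6", "FC2", "CZ", "C4", "T8", "CP6", "CP2", "P4", "P8",
      "PO4", "O2"
    ),
    seed62 = c(
      "FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F5", "F3", "F1", "FZ",
      "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2",
      "FC4", "FC6", "FT8", "T7", "C5", "C3", "C1", "CZ", "C2", "C4",
      "C6", "T8", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
      "TP8", "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
      "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8", "CB1", "O1", "OZ",
      "O2", "CB2"
    )
  )
  if (!layout_id %in% names(layouts)) {
    stop(sprintf(
      "unknown layout_id '%s'; known layouts: {%s}",
      layout_id, paste(names(layouts), collapse = ", ")
    ), call. = FALSE)
  }
  electrodes <- layouts[[layout_id]]
  stopifnot(!anyDuplicated(electrodes))
  idx <- seq_along(electrodes)
  names(idx) <- electrodes
  structure(
    list(layout_id = layout_id, electrodes = electrodes, channel_index = idx),
    class = "eeg_layout"
  )
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat(sprintf(
    "<eeg_layout '%s': %d electrodes>\n", x$layout_id, length(x$electrodes)
  ))
  invisible(x)
}

canon_electrode <- function(x) toupper(trimws(x))

new_region_partition <- function(layout_id, regions) {
  names(regions) <- vapply(regions, function(r) r$name, character(1))
  elec <- lapply(regions, function(r) canon_electrode(r$electrodes))
  structure(
    list(
      layout_id = layout_id,
      region_names = names(regions),
      regions = elec
    ),
    class = "region_partition"
  )
}

#' Build a packaged electrode-to-region partition
#'
#' Returns the ordered grouping of electrodes into brain regions used by the
#' regional feature-learning layers. Both packaged partitions have 12 regions
#' (pre-frontal through occipital); `deap32` covers all 32 electrodes, while
#' `seed62` enumerates 60 of the 62 montage electrodes (see
#' [validate_partition()], which reports the two unpartitioned electrodes as
#' an informational note).
#'
#' Region order and within-region electrode order are fixed: the BiLSTM
#' encoders run over channels in this order, so the ordering is part of the
#' model definition.
#'
#' @param layout_id One of `"deap32"`, `"seed62"`, or a path to a JSON file
#'   in the partition schema
#'   `{layout_id, regions: [{name, electrodes: [...]}]}`.
#' @return A `region_partition`: ordered named list of electrode vectors with
#'   the source `layout_id`.
#' @export
build_partition <- function(layout_id) {
  known <- c("deap32", "seed62")
  if (layout_id %in% known) {
    path <- system.file(
      "extdata", "partitions", paste0(layout_id, ".json"),
      package = "eegr2g", mustWork = TRUE
    )
  } else if (file.exists(layout_id)) {
    path <- layout_id
  } else {
    stop(sprintf(
      "unknown layout_id '%s'; known layouts: {%s}",
      layout_id, paste(known, collapse = ", ")
    ), call. = FALSE)
  }
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- lapply(seq_len(nrow(spec$regions)), function(i) {
    list(
      name = spec$regions$name[i],
      electrodes = unlist(spec$regions$electrodes[i])
    )
  })
  part <- new_region_partition(spec$layout_id, regions)
  dup <- anyDuplicated(unlist(part$regions))
  if (dup) stop("partition has duplicated electrodes", call. = FALSE)
  part
}

#' Number of regions and region sizes
#'
#' @param partition A `region_partition`.
#' @return `n_regions()` the number of regions; `region_sizes()` a named
#'   integer vector of electrodes per region.
#' @export
n_regions <- function(partition) length(partition$regions)

#' @rdname n_regions
#' @export
region_sizes <- function(partition) {
  vapply(partition$regions, length, integer(1))
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "<region_partition '%s': %d regions, %d electrodes>\n",
    x$layout_id, n_regions(x), sum(region_sizes(x))
  ))
  sz <- region_sizes(x)
  for (i in seq_along(x$regions)) {
    cat(sprintf(
      "  %2d %-19s [%s]\n", i, x$region_names[i],
      paste(x$regions[[i]], collapse = ", ")
    ))
  }
  invisible(x)
}

#' Look up the region containing an electrode
#'
#' @param electrode Electrode name (case-insensitive).
#' @param partition A `region_partition`.
#' @return 1-based index of the containing region, named with the region
#'   name. Errors if the electrode is absent from the partition.
#' @export
region_of <- function(electrode, partition) {
  e <- canon_electrode(electrode)
  hits <- which(vapply(partition$regions, function(r) e %in% r, logical(1)))
  if (length(hits) == 0) {
    stop(sprintf(
      "electrode '%s' is not assigned to any region of partition '%s'",
      electrode, partition$layout_id
    ), call. = FALSE)
  }
  if (length(hits) > 1) {
    stop(sprintf("electrode '%s' appears in %d regions", electrode,
                 length(hits)), call. = FALSE)
  }
  stats::setNames(hits, partition$region_names[hits])
}

#' Validate a partition against an electrode layout
#'
#' Report-style validation: disjointness of regions, minimum region size of
#' two electrodes, and membership of every partitioned electrode in the
#' layout. Electrodes present in the layout but absent from the partition are
#' reported as informational notes (not violations) — e.g. the packaged
#' `seed62` partition enumerates 60 of the 62 montage electrodes.
#'
#' @param partition A `region_partition`.
#' @param layout An `eeg_layout` (defaults to the partition's own layout).
#' @return A data.frame with columns `severity` (`"violation"` or `"note"`),
#'   `rule`, and `detail`; zero violation rows means the partition is valid.
#' @export
validate_partition <- function(partition,
                               layout = electrode_layout(partition$layout_id)) {
  rows <- list()
  add <- function(severity, rule, detail) {
    rows[[length(rows) + 1]] <<- data.frame(
      severity = severity, rule = rule, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  all_e <- unlist(partition$regions, use.names = FALSE)
  dups <- unique(all_e[duplicated(all_e)])
  for (d in dups) {
    add("violation", "disjointness",
        sprintf("electrode '%s' appears in more than one region", d))
  }
  sz <- region_sizes(partition)
  for (i in which(sz < 2)) {
    add("violation", "min_size_2",
        sprintf("region '%s' has %d electrode(s); at least 2 required",
                partition$region_names[i], sz[i]))
  }
  missing <- setdiff(unique(all_e), canon_electrode(layout$electrodes))
  for (m in missing) {
    add("violation", "layout_membership",
        sprintf("electrode '%s' is not in layout '%s'", m, layout$layout_id))
  }
  unused <- setdiff(canon_electrode(layout$electrodes), all_e)
  if (length(unused) > 0) {
    add("note", "unpartitioned_electrodes",
        sprintf("%d layout electrode(s) not assigned to any region: %s",
                length(unused), paste(unused, collapse = ", ")))
  }
  if (length(rows) == 0) {
    return(data.frame(severity = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Channel indices of each region within a layout
#'
#' Maps a partition onto the raw-array column indices of a layout, in region
#' order then within-region order.
#'
#' @inheritParams validate_partition
#' @return Named list of integer index vectors, one per region.
#' @export
region_channel_indices <- function(partition,
                                   layout = electrode_layout(partition$layout_id)) {
  idx <- layout$channel_index
  names(idx) <- canon_electrode(names(idx))
  lapply(partition$regions, function(r) {
    miss <- setdiff(r, names(idx))
    if (length(miss) > 0) {
      stop(sprintf("electrodes not in layout '%s': %s", layout$layout_id,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    unname(idx[r])
  })
}
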