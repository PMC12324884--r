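#' Read a Web-of-Life style incidence matrix
#'
#' Parses the CSV dialect used by plant-pollinator incidence tables: the first
#' row holds animal labels, the first column plant labels, and cells hold
#' interaction records (visit counts or 0/1). Any cell greater than zero is
#' binarized to 1; the model uses only the binary incidence, interaction
#' strengths being drawn independently at assembly.
#'
#' @param path path to a CSV file.
#' @return a [bipartite_network()].
#' @export
read_incidence_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop("incidence file needs a header row and at least one plant row",
         call. = FALSE)
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- trimws(cells[[1]])
  animal_ids <- header[-1]
  if (length(animal_ids) < 1) stop("no animal columns in header", call. = FALSE)
  ncols <- length(header)
  rows <- cells[-1]
  plant_ids <- character(length(rows))
  inc <- matrix(0, length(rows), length(animal_ids))
  for (i in seq_along(rows)) {
    row <- trimws(rows[[i]])
    if (length(row) != ncols) {
      stop(sprintf("ragged row %d ('%s'): expected %d cells, found %d",
                   i + 1, row[1], ncols, length(row)), call. = FALSE)
    }
    plant_ids[i] <- row[1]
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   row[1], animal_ids[bad]), call. = FALSE)
    }
    inc[i, ] <- as.numeric(vals > 0)
  }
  bipartite_network(inc, plant_ids, animal_ids)
}

#' Write a network in the Web-of-Life incidence dialect
#'
#' @param net a [bipartite_network()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_incidence_matrix <- function(net, path) {
  header <- paste(c("", net$animal_ids), collapse = ",")
  body <- vapply(seq_len(n_plants(net)), function(i) {
    paste(c(net$plant_ids[i], format(net$incidence[i, ], trim = TRUE)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Network edge list as a tibble
#'
#' One row per mutualistic link, for trajectory snapshots and plotting.
#' @param net a [bipartite_network()].
#' @return tibble with columns `plant_id`, `animal_id`.
#' @export
as_edge_list <- function(net) {
  idx <- which(net$incidence == 1, arr.ind = TRUE)
  tibble::tibble(
    plant_id = net$plant_ids[idx[, 1]],
    animal_id = net$animal_ids[idx[, 2]]
  ) |> dplyr::arrange(.data$plant_id, .data$animal_id)
}

#' Write a network edge list CSV
#' @param net a [bipartite_network()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  write.csv(as_edge_list(net), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
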