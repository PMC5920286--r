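AGE_GROUPS_ALLOC <- c("35-64", "65-74", "75-84", "85+")

allocation_age_group <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 64, 74, 84, Inf),
      labels = AGE_GROUPS_ALLOC, right = TRUE)
}

#' Dementia allocation table
#'
#' Probabilities of dementia by age group (`35-64, 65-74, 75-84, 85+`),
#' MMSE band (`0-20, 21-25, 26-30`) and residence
#' (`community, care_home`). Cells must be exhaustive over the three
#' dimensions.
#'
#' @param table data frame with columns `age_group`, `mmse_band`,
#'   `residence`, `p`.
#' @return validated table of class `allocation_table`.
#' @export
allocation_table <- function(table) {
  need <- c("age_group", "mmse_band", "residence", "p")
  if (!all(need %in% names(table)))
    .input_error("allocation table needs columns age_group, mmse_band, residence, p")
  if (any(table$p < 0 | table$p > 1))
    .domain_error("allocation probabilities outside [0, 1]")
  full <- expand.grid(age_group = AGE_GROUPS_ALLOC, mmse_band = MMSE_BANDS,
                      residence = c("community", "care_home"),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$age_group, d$mmse_band, d$residence)
  missing_cells <- setdiff(key(full), key(table))
  if (length(missing_cells))
    .input_error(paste0("allocation table missing cell(s): ",
                        paste(missing_cells, collapse = "; ")))
  class(table) <- c("allocation_table", "data.frame")
  table
}

#' Default synthetic dementia allocation table
#'
#' Probabilities rise with age band, are highest at low MMSE and higher in
#' care homes. This is a synthetic stand-in chosen to yield a 65+ dementia
#' prevalence of a few percent in the generated populations; it is not
#' estimated from any cognitive-ageing study.
#'
#' @return an `allocation_table`.
#' @export
default_allocation_table <- function() {
  tab <- expand.grid(age_group = AGE_GROUPS_ALLOC, mmse_band = MMSE_BANDS,
                     residence = c("community", "care_home"),
                     stringsAsFactors = FALSE)
  base <- matrix(c( # rows: age groups; cols: mmse bands 0-20, 21-25, 26-30
    0.050, 0.005, 0.0005,
    0.150, 0.030, 0.005,
    0.350, 0.100, 0.020,
    0.600, 0.250, 0.060), nrow = 4, byrow = TRUE,
    dimnames = list(AGE_GROUPS_ALLOC, MMSE_BANDS))
  care <- matrix(c(
    0.300, 0.100, 0.020,
    0.500, 0.150, 0.050,
    0.700, 0.300, 0.100,
    0.850, 0.500, 0.200), nrow = 4, byrow = TRUE,
    dimnames = list(AGE_GROUPS_ALLOC, MMSE_BANDS))
  tab$p <- ifelse(tab$residence == "community",
                  base[cbind(tab$age_group, tab$mmse_band)],
                  care[cbind(tab$age_group, tab$mmse_band)])
  allocation_table(tab)
}

#' Read / write an allocation table CSV
#'
#' @param path file path.
#' @param table an `allocation_table`.
#' @return `read_allocation_table` returns a validated table.
#' @export
read_allocation_table <- function(path) {
  allocation_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                   comment.char = "#"))
}

#' @rdname read_allocation_table
#' @export
write_allocation_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

allocation_cell_prob <- function(pop, table) {
  key <- paste(allocation_age_group(pop$age_months %/% 12L),
               MMSE_BANDS[mmse_band_index(pop$mmse)], pop$residence)
  tab_key <- paste(table$age_group, table$mmse_band, table$residence)
  i <- match(key, tab_key)
  if (anyNA(i))
    .input_error(paste0("no allocation cell for: ",
                        paste(unique(key[is.na(i)]), collapse = "; ")))
  table$p[i]
}

#' Allocate dementia status probabilistically, outside the simulation
#'
#' Dementia is assigned after the simulation, conditional on age group,
#' MMSE band and residence. In `"persistent"` mode (default) each
#' individual carries a single uniform quantile `u` drawn once per run, and
#' in every snapshot dementia = (`u` < cell probability); because cell
#' probabilities rise along a trajectory of increasing age and
#' non-increasing MMSE, onset is then effectively monotone across snapshot
#' years. `"independent"` mode draws afresh per snapshot.
#'
#' @param x a `simulation_output`, a named list of snapshot populations, or
#'   a single population data frame.
#' @param table an [allocation_table()].
#' @param seed integer seed for the allocation quantiles.
#' @param mode `"persistent"` or `"independent"`.
#' @return `x` with the `dementia` flag set in every snapshot.
#' @export
allocate_dementia <- function(x, table = default_allocation_table(),
                              seed = 1L, mode = c("persistent", "independent")) {
  mode <- match.arg(mode)
  if (inherits(x, "simulation_output")) {
    x$snapshots <- allocate_dementia(x$snapshots, table, seed, mode)
    return(x)
  }
  single <- is.data.frame(x)
  snaps <- if (single) list(x) else x
  ids <- sort(unique(unlist(lapply(snaps, `[[`, "id"))))
  set.seed(seed)
  u_all <- stats::setNames(runif(length(ids)), ids)
  out <- lapply(snaps, function(snap) {
    p <- allocation_cell_prob(snap, table)
    u <- if (mode == "persistent") u_all[as.character(snap$id)]
         else runif(nrow(snap))
    snap$dementia <- unname(u < p)
    snap
  })
  if (single) out[[1]] else out
}
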