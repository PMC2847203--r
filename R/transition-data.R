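#' Yearly-aggregated multinomial transition data
#'
#' The observation unit is one (patient, year, from-state) multinomial row:
#' the number of days the patient spent in `from_state` during follow-up year
#' `year`, split by the state occupied on the next day.  Covariates are
#' constant within a row (time-dependent age is recorded as the age in that
#' year).
#'
#' @param df data frame with columns `patient`, `year`, `from_state`, count
#'   columns `n1..nR` (one per destination state), and covariate columns
#'   (including `age` when used).
#' @param space the [state_space()] the counts live on.
#' @return object of class `transition_data` (a validated data frame).
#' @export
transition_data <- function(df, space) {
  stopifnot(inherits(space, "state_space"))
  R <- space$n
  cnt_cols <- paste0("n", seq_len(R))
  need <- c("patient", "year", "from_state", cnt_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("transition data lacks column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  counts <- as.matrix(df[cnt_cols])
  if (any(counts < 0)) stopf("negative transition count (row %d)", which(rowSums(counts < 0) > 0)[1L])
  if (any(df$from_state %in% space$absorbing & rowSums(counts) > 0))
    stopf("transitions out of an absorbing state")
  allowed <- matrix(FALSE, R, R)
  allowed[space$permitted] <- TRUE
  viol <- counts > 0 & !allowed[df$from_state, , drop = FALSE]
  if (any(viol)) {
    i <- which(rowSums(viol) > 0)[1L]
    s <- which(viol[i, ])[1L]
    stopf("row %d: %d transition(s) on non-permitted pair (%d,%d)",
          i, counts[i, s], df$from_state[i], s)
  }
  df$N <- rowSums(counts)
  structure(df, class = c("transition_data", "data.frame"),
            space = space,
            cov_cols = setdiff(names(df), c(need, "N")))
}

#' @export
print.transition_data <- function(x, ...) {
  cat(sprintf("transition data: %d multinomial rows, %d patients, %d days observed\n",
              nrow(x), length(unique(x$patient)), sum(x$N)))
  invisible(x)
}

#' Read / write transition data as long-format CSV
#'
#' The on-disk dialect is long in the destination state: columns `patient`,
#' `year`, `from_state`, `to_state`, `count`, plus covariate columns.  The
#' reader aggregates to multinomial rows; zero-count destinations need not be
#' present.
#'
#' @param path CSV path.
#' @param space the [state_space()] of the counts.
#' @param data a `transition_data` object.
#' @return `read_transition_csv` returns a [transition_data()].
#' @export
read_transition_csv <- function(path, space) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "year", "from_state", "to_state", "count")
  miss <- setdiff(need, names(long))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  R <- space$n
  bad <- which(!(long$to_state %in% seq_len(R)) | !(long$from_state %in% seq_len(R)))
  if (length(bad)) stopf("%s: state index out of range at data row %d", path, bad[1L])
  allowed <- matrix(FALSE, R, R)
  allowed[space$permitted] <- TRUE
  bad <- which(long$count > 0 & !allowed[cbind(long$from_state, long$to_state)])
  if (length(bad))
    stopf("%s: count on non-permitted transition (%d,%d) at data row %d",
          path, long$from_state[bad[1L]], long$to_state[bad[1L]], bad[1L])
  covs <- setdiff(names(long), need)
  key_cols <- c("patient", "year", "from_state", covs)
  key <- do.call(paste, c(long[key_cols], sep = "\r"))
  idx <- match(key, unique(key))
  wide <- long[!duplicated(key), key_cols, drop = FALSE]
  counts <- matrix(0, nrow = nrow(wide), ncol = R,
                   dimnames = list(NULL, paste0("n", seq_len(R))))
  for (j in seq_len(nrow(long)))
    counts[idx[j], long$to_state[j]] <- counts[idx[j], long$to_state[j]] + long$count[j]
  transition_data(cbind(wide, counts), space)
}

#' @rdname read_transition_csv
#' @export
write_transition_csv <- function(data, path) {
  space <- attr(data, "space")
  R <- space$n
  covs <- attr(data, "cov_cols")
  rows <- list()
  counts <- as.matrix(data[paste0("n", seq_len(R))])
  for (i in seq_len(nrow(data))) {
    s <- which(counts[i, ] > 0)
    if (!length(s)) next
    rows[[length(rows) + 1L]] <-
      data.frame(patient = data$patient[i], year = data$year[i],
                 from_state = data$from_state[i], to_state = s,
                 count = counts[i, s], data[i, covs, drop = FALSE],
                 row.names = NULL)
  }
  long <- do.call(rbind, rows)
  write.csv(long[order(long$patient, long$year, long$from_state, long$to_state), ],
            path, row.names = FALSE)
  invisible(path)
}
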