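# Plain-text I/O for the pipeline's standard containers.

#' Read 21-depth profiles from TSV
#'
#' Expects columns `vertex_id`, `d0` ... `d20` (superficial to deep).
#'
#' @param path TSV file path.
#' @return numeric matrix vertices x 21 with vertex ids as rownames.
#' @export
read_profiles_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  depth_cols <- grep("^d[0-9]+$", names(df), value = TRUE)
  depth_cols <- depth_cols[order(as.integer(sub("^d", "", depth_cols)))]
  m <- as.matrix(df[, depth_cols, drop = FALSE])
  rownames(m) <- df$vertex_id
  m
}

#' Write 21-depth profiles to TSV
#' @param profiles numeric matrix vertices x depths.
#' @param path output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  df <- data.frame(vertex_id = seq_len(nrow(profiles)), profiles)
  names(df) <- c("vertex_id", paste0("d", seq_len(ncol(profiles)) - 1L))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Serialize a compartment scheme to JSON
#' @param compartments a [compartmentalize_profile()] result.
#' @param path output path.
#' @export
write_compartments_json <- function(compartments, path) {
  jsonlite::write_json(
    list(b1 = compartments$b1, b2 = compartments$b2,
         f1 = compartments$f1, f2 = compartments$f2,
         spans = as.list(compartments$spans)),
    path, auto_unbox = TRUE, digits = NA)
}

#' Serialize a border report to JSON
#' @param borders list of (classified) borders.
#' @param path output path.
#' @export
write_borders_json <- function(borders, path) {
  rep <- lapply(borders, function(b) {
    list(class = if (is.null(b$class)) NA else b$class,
         position = b$position, paths = b$paths,
         features = if (is.null(b$features)) NULL else as.list(b$features),
         members = b$members)
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
}
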