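#' Load a dataset manifest
#'
#' Two layouts are supported. The directory convention expects `train/` and
#' `test/` subdirectories of `root` containing PNG/JPEG files; an optional
#' category label is parsed from file names of the form
#' `<stem>_<category>.<ext>`. Alternatively `listing` names a CSV file with
#' columns `path,split[,category]`, with paths relative to `root`.
#'
#' Entries are sorted (split, then path) so the manifest order is identical
#' across runs and platforms.
#'
#' @param root dataset root directory.
#' @param listing optional path to a CSV listing file.
#' @param checkDecodes if `TRUE`, additionally decode every file (slow).
#' @return A [DatasetManifest-class].
#' @export
loadManifest <- function(root, listing = NULL, checkDecodes = FALSE) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  if (is.null(listing)) {
    entries <- do.call(rbind, lapply(c("train", "test"), function(sp) {
      dd <- file.path(root, sp)
      files <- if (dir.exists(dd))
        sort(list.files(dd, pattern = "\\.(png|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE))
      else character(0)
      if (length(files) == 0L)
        stop("empty split '", sp, "' under ", root)
      stem <- tools::file_path_sans_ext(basename(files))
      cat_lab <- ifelse(grepl("_", stem), sub("^.*_", "", stem), NA_character_)
      data.frame(path = files, split = sp, category = cat_lab,
                 stringsAsFactors = FALSE)
    }))
  } else {
    if (!file.exists(listing)) stop("listing file not found: ", listing)
    tab <- utils::read.csv(listing, stringsAsFactors = FALSE)
    if (!all(c("path", "split") %in% names(tab)))
      stop("listing must have columns path,split[,category]")
    if (is.null(tab$category)) tab$category <- NA_character_
    tab$path <- file.path(root, tab$path)
    for (sp in c("train", "test"))
      if (!any(tab$split == sp)) stop("empty split '", sp, "' in listing")
    entries <- tab[order(tab$split, tab$path),
                   c("path", "split", "category")]
  }
  missing <- entries$path[!file.exists(entries$path)]
  if (length(missing) > 0L)
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))
  if (checkDecodes) for (p in entries$path) readRaster(p)
  rownames(entries) <- NULL
  new("DatasetManifest", entries = entries, root = root)
}

#' @describeIn loadManifest entry table accessor
#' @param manifest a `DatasetManifest`
#' @export
manifestEntries <- function(manifest) manifest@entries

#' @describeIn loadManifest paths of one split
#' @param split `"train"` or `"test"`
#' @export
manifestPaths <- function(manifest, split = c("train", "test")) {
  split <- match.arg(split)
  manifest@entries$path[manifest@entries$split == split]
}

setMethod("show", "DatasetManifest", function(object) {
  tab <- table(object@entries$split)
  cat(sprintf("DatasetManifest: %d entries (%s) under %s\n",
              nrow(object@entries),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              object@root))
})
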