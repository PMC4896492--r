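# Locate the deposited electrode-level MAT datasets, if the user has placed
# them in the repository. They are third-party supplementary downloads and are
# not distributed with the package.
find_supplementary <- function() {
  roots <- c(
    file.path(testthat::test_path(), "..", "..", "supplementary"),
    file.path(testthat::test_path(), "supplementary"),
    system.file("extdata", "supplementary", package = "gammasel")
  )
  for (root in roots) {
    if (!nzchar(root) || !dir.exists(root)) next
    f <- function(pat) {
      hit <- list.files(root, pattern = pat, ignore.case = TRUE,
                        full.names = TRUE)
      if (length(hit)) hit[1] else NA_character_
    }
    paths <- c(vtc_left = f("^S1.*\\.mat$"), vtc_right = f("^S2.*\\.mat$"),
               loc = f("^S3.*\\.mat$"))
    if (!anyNA(paths)) return(as.list(paths))
  }
  NULL
}

missing_supplementary_msg <- paste(
  "The deposited electrode-level datasets (S1-S3 MAT files) are not present.",
  "They are third-party binary downloads and cannot ship with this package;",
  "place them as supplementary/S1.mat, S2.mat, S3.mat at the repository root",
  "to run this reproduction."
)
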