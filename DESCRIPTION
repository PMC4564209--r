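Package: voxalign
Title: Correlation-Ratio Affine and Local-Correlation Deformable Brain Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intensity-based 3-D registration of brain MR volumes. Implements
    the correlation ratio similarity metric through an intensity-sorted,
    bin-partitioned reduction inside a multistart multiresolution affine
    search over an 8/4/2/1 mm pyramid, and the local windowed squared
    cross-correlation metric (five sliding-window sums and its A/B/C
    decomposition) driving a simplified symmetric deformable refinement in
    which two half-way displacement fields warp both images toward a
    midpoint. Includes NIfTI-1 input/output, trilinear resampling, a
    deterministic brain-like phantom generator with known ground-truth
    transforms, and registration assessment by mean absolute difference and
    Jaccard label overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
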