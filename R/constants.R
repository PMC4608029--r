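# Package-wide constants.

# The seven empirical minicircle shape classes, in order of increasing
# compactness (this order defines the weighted-compactness weights 1..7).
SHAPE_CLASSES <- c("open_circle", "open_figure8", "figure8", "racquet",
                   "handcuffs", "needle", "rod")

# B-form DNA duplex radius (A); generated loop radii below this are
# rejected as infeasible, and it is the default tube sigma for phantoms.
DNA_TUBE_RADIUS <- 10
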