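format-version: 1.2
data-version: toy-immune-1.0

[Term]
id: alveolar macrophage
name: alveolar macrophage
is_a: macrophage

[Term]
id: B cell
name: B cell
is_a: lymphocyte

[Term]
id: basophil
name: basophil
is_a: myeloid leukocyte

[Term]
id: CD4 T cell
name: CD4 T cell
is_a: T cell

[Term]
id: CD8 T cell
name: CD8 T cell
is_a: T cell

[Term]
id: cell
name: cell

[Term]
id: ciliated cell
name: ciliated cell
is_a: epithelial cell

[Term]
id: classical monocyte
name: classical monocyte
is_a: monocyte

[Term]
id: dendritic cell
name: dendritic cell
is_a: myeloid leukocyte

[Term]
id: endothelial cell
name: endothelial cell
is_a: stromal cell

[Term]
id: eosinophil
name: eosinophil
is_a: myeloid leukocyte

[Term]
id: epithelial cell
name: epithelial cell
is_a: cell

[Term]
id: fibroblast
name: fibroblast
is_a: stromal cell

[Term]
id: gamma-delta T cell
name: gamma-delta T cell
is_a: T cell

[Term]
id: inflammatory macrophage
name: inflammatory macrophage
is_a: macrophage

[Term]
id: leukocyte
name: leukocyte
is_a: cell

[Term]
id: lymphocyte
name: lymphocyte
is_a: leukocyte

[Term]
id: macrophage
name: macrophage
is_a: myeloid leukocyte

[Term]
id: memory B cell
name: memory B cell
is_a: B cell

[Term]
id: monocyte
name: monocyte
is_a: myeloid leukocyte

[Term]
id: myeloid leukocyte
name: myeloid leukocyte
is_a: leukocyte

[Term]
id: naive B cell
name: naive B cell
is_a: B cell

[Term]
id: natural killer cell
name: natural killer cell
is_a: lymphocyte

[Term]
id: neutrophil
name: neutrophil
is_a: myeloid leukocyte

[Term]
id: non-classical monocyte
name: non-classical monocyte
is_a: monocyte

[Term]
id: plasma cell
name: plasma cell
is_a: B cell

[Term]
id: regulatory T cell
name: regulatory T cell
is_a: T cell

[Term]
id: secretory cell
name: secretory cell
is_a: epithelial cell

[Term]
id: stromal cell
name: stromal cell
is_a: cell

[Term]
id: T cell
name: T cell
is_a: lymphocyte

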