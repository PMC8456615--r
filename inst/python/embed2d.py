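"""Two-dimensional embedding helper (t-SNE via scikit-learn, UMAP via
umap-learn). Reads a headerless TSV matrix (samples x features), writes a
headerless TSV (samples x 2)."""
import argparse

import numpy as np


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--input", required=True)
    ap.add_argument("--output", required=True)
    ap.add_argument("--method", choices=["tsne", "umap"], required=True)
    ap.add_argument("--seed", type=int, default=1)
    ap.add_argument("--perplexity", type=float, default=20)
    ap.add_argument("--learning_rate", type=float, default=300)
    ap.add_argument("--max_iter", type=int, default=400)
    ap.add_argument("--n_neighbors", type=int, default=50)
    ap.add_argument("--min_dist", type=float, default=0.3)
    ap.add_argument("--metric", default="euclidean")
    args = ap.parse_args()

    X = np.loadtxt(args.input, delimiter="\t", ndmin=2)
    if args.method == "tsne":
        from sklearn.manifold import TSNE

        emb = TSNE(
            n_components=2,
            init="pca",
            perplexity=args.perplexity,
            learning_rate=args.learning_rate,
            max_iter=args.max_iter,
            random_state=args.seed,
        ).fit_transform(X)
    else:
        from umap import UMAP

        emb = UMAP(
            n_components=2,
            n_neighbors=args.n_neighbors,
            min_dist=args.min_dist,
            metric=args.metric,
            random_state=args.seed,
        ).fit_transform(X)
    np.savetxt(args.output, emb, delimiter="\t")


if __name__ == "__main__":
    main()
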