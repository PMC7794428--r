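#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 8-connected component labelling of a logical matrix by BFS.
// Returns an integer matrix of the same shape: 0 = background,
// components numbered 1..k in raster (column-major) discovery order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix img) {
    int nr = img.nrow(), nc = img.ncol();
    IntegerMatrix lab(nr, nc);
    int next = 0;
    std::vector<int> stack;
    stack.reserve(256);

    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!img(r, c) || lab(r, c) != 0) continue;
            ++next;
            lab(r, c) = next;
            stack.push_back(c * nr + r);
            while (!stack.empty()) {
                int idx = stack.back();
                stack.pop_back();
                int rr = idx % nr, cc = idx / nr;
                for (int dc = -1; dc <= 1; ++dc) {
                    for (int dr = -1; dr <= 1; ++dr) {
                        if (dr == 0 && dc == 0) continue;
                        int r2 = rr + dr, c2 = cc + dc;
                        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
                        if (img(r2, c2) && lab(r2, c2) == 0) {
                            lab(r2, c2) = next;
                            stack.push_back(c2 * nr + r2);
                        }
                    }
                }
            }
        }
    }
    return lab;
}
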