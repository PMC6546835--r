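#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass 8-connected labelling with union-find. Labels are assigned in
// raster order and compacted to 1..n, so they are stable for a fixed input.

static int uf_find(std::vector<int>& parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra == rb) return;
    if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> parent;
    parent.push_back(0); // dummy so labels start at 1

    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!mask(r, c)) continue;
            // previously visited 8-neighbours in column-major raster order:
            // (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
            int best = 0;
            int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
            for (int k = 0; k < 4; ++k) {
                int rr = nb[k][0], cc = nb[k][1];
                if (rr < 0 || rr >= nr || cc < 0) continue;
                int l = lab(rr, cc);
                if (l > 0) {
                    if (best == 0) best = l;
                    else uf_union(parent, best, l);
                }
            }
            if (best == 0) {
                int nl = (int)parent.size();
                parent.push_back(nl);
                lab(r, c) = nl;
            } else {
                lab(r, c) = best;
            }
        }
    }

    // compact root labels to 1..n in order of first appearance (raster order)
    std::vector<int> remap(parent.size(), 0);
    int next = 0;
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            int l = lab(r, c);
            if (l == 0) continue;
            int root = uf_find(parent, l);
            if (remap[root] == 0) remap[root] = ++next;
            lab(r, c) = remap[root];
        }
    }
    return lab;
}

// Binary dilation by a (2k+1)x(2k+1) square structuring element
// (Chebyshev ball), the conventional pixel-dilation used for contact tests.

// [[Rcpp::export(name = ".dilate_square_cpp")]]
LogicalMatrix dilate_square_cpp(LogicalMatrix mask, int k) {
    int nr = mask.nrow(), nc = mask.ncol();
    LogicalMatrix out(nr, nc);
    if (k <= 0) {
        for (int i = 0; i < nr * nc; ++i) out[i] = mask[i];
        return out;
    }
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!mask(r, c)) continue;
            int r0 = std::max(0, r - k), r1 = std::min(nr - 1, r + k);
            int c0 = std::max(0, c - k), c1 = std::min(nc - 1, c + k);
            for (int cc = c0; cc <= c1; ++cc)
                for (int rr = r0; rr <= r1; ++rr)
                    out(rr, cc) = true;
        }
    }
    return out;
}

// 3x3 median filter with edge replication — the classic despeckle step
// applied before thresholding; removes isolated noise pixels without
// systematically shifting region areas.

// [[Rcpp::export(name = ".median3_cpp")]]
NumericMatrix median3_cpp(NumericMatrix img) {
    int nr = img.nrow(), nc = img.ncol();
    NumericMatrix out(nr, nc);
    double win[9];
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            int k = 0;
            for (int dc = -1; dc <= 1; ++dc) {
                int cc = std::min(std::max(c + dc, 0), nc - 1);
                for (int dr = -1; dr <= 1; ++dr) {
                    int rr = std::min(std::max(r + dr, 0), nr - 1);
                    win[k++] = img(rr, cc);
                }
            }
            std::nth_element(win, win + 4, win + 9);
            out(r, c) = win[4];
        }
    }
    return out;
}

// Binary erosion by a (2k+1)x(2k+1) square element; pixels outside the
// image count as background, so erosion shrinks regions at the borders.

// [[Rcpp::export(name = ".erode_square_cpp")]]
LogicalMatrix erode_square_cpp(LogicalMatrix mask, int k) {
    int nr = mask.nrow(), nc = mask.ncol();
    LogicalMatrix out(nr, nc);
    if (k <= 0) {
        for (int i = 0; i < nr * nc; ++i) out[i] = mask[i];
        return out;
    }
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!mask(r, c)) continue;
            bool keep = true;
            for (int cc = c - k; keep && cc <= c + k; ++cc) {
                if (cc < 0 || cc >= nc) { keep = false; break; }
                for (int rr = r - k; rr <= r + k; ++rr) {
                    if (rr < 0 || rr >= nr || !mask(rr, cc)) { keep = false; break; }
                }
            }
            out(r, c) = keep;
        }
    }
    return out;
}
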