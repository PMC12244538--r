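// Optional control of OpenBLAS threading. The network kernels issue many
// small GEMMs, where BLAS thread synchronization costs far more than the
// arithmetic; training pins BLAS to one thread and restores the previous
// setting afterwards. No-ops when the BLAS does not expose the OpenBLAS
// entry points.

#include <Rcpp.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif

// [[Rcpp::export]]
int blas_get_threads() {
#ifndef _WIN32
  typedef int (*get_t)(void);
  get_t f = (get_t)dlsym(RTLD_DEFAULT, "openblas_get_num_threads");
  if (f) return f();
#endif
  return -1;
}

// [[Rcpp::export]]
void blas_set_threads(int n) {
#ifndef _WIN32
  typedef void (*set_t)(int);
  set_t f = (set_t)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f && n > 0) f(n);
#endif
}
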