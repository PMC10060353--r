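# Build with the system toolchain: the bundled cross-compiler targets a
# newer glibc than the runtime loader provides, so its objects cannot be
# dyn.load()ed.  `override` is needed because this file is read before
# the R Makeconf that sets the default compilers.
override CXX = g++ -std=gnu++17
override CXX17 = g++
override CC = gcc
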